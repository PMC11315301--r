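# GAN training: alternating hinge-loss updates of generator and
# discriminator on normal slices only.

#' GAN training configuration
#'
#' Defaults are the full-scale training conditions: batch size 8, 100,000
#' steps, learning rate 2e-4 with Adam, a 512-dimensional latent space with
#' uniform prior on \[-1,1\], and mirroring/contrast/translation augmentation.
#' Smaller study sizes are configured explicitly by the caller.
#'
#' @param resolution working image resolution (power of two >= 16).
#' @param latent_dim latent dimension L.
#' @param batch_size images per step.
#' @param steps number of alternating update steps.
#' @param lr Adam learning rate.
#' @param betas Adam moment decay rates.
#' @param base_channels,channel_cap width plan of both networks.
#' @param noise_injection enable per-block learned noise in the generator.
#' @param augment an [augment_config()].
#' @param seed RNG seed for the full training run.
#' @param checkpoint_every checkpoint cadence in steps.
#' @param checkpoint_dir directory for checkpoints (NULL: keep none).
#' @export
gan_config <- function(resolution = 512, latent_dim = 512, batch_size = 8,
                       steps = 100000, lr = 2e-4, betas = c(0.5, 0.999),
                       base_channels = 32, channel_cap = 256,
                       noise_injection = TRUE, augment = augment_config(),
                       seed = 1, checkpoint_every = 1000,
                       checkpoint_dir = NULL) {
  .check_pow2(resolution)
  stopifnot(latent_dim >= 1, batch_size >= 1, steps >= 1, lr > 0,
            length(betas) == 2, checkpoint_every >= 1)
  structure(list(resolution = resolution, latent_dim = latent_dim,
                 batch_size = batch_size, steps = steps, lr = lr,
                 betas = betas, base_channels = base_channels,
                 channel_cap = channel_cap, noise_injection = noise_injection,
                 augment = augment, seed = seed,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir), class = "gan_config")
}

#' Sample latent vectors from the uniform prior
#'
#' Components are i.i.d. uniform on \[-1,1\].
#'
#' @param n number of vectors.
#' @param dim latent dimension.
#' @param seed optional seed; when given, the global RNG state is restored
#'   afterwards.
#' @return `dim x n` matrix, one latent vector per column.
#' @export
sample_latent <- function(n, dim = 512, seed = NULL) {
  stopifnot(n >= 1, dim >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  matrix(stats::runif(n * dim, -1, 1), dim, n)
}

# assemble an [N,N,1,B] batch from dataset images, with augmentation
.make_batch <- function(images, idx, aug = NULL) {
  N <- nrow(images[[idx[1]]])
  x <- array(0, c(N, N, 1L, length(idx)))
  for (j in seq_along(idx)) {
    im <- images[[idx[j]]]
    if (!is.null(aug)) im <- augment(im, aug)
    x[, , 1L, j] <- im
  }
  x
}

#' Train the GAN on a normal-only dataset
#'
#' Alternates one discriminator update (hinge loss on real and generated
#' batches plus the auxiliary decoder reconstruction loss on real images) with
#' one generator update (negative mean logit) per step.  Fully seeded: two
#' runs with the same configuration and dataset are identical.
#'
#' @param dataset a training [slice_dataset()] (split "train", no masks).
#' @param config a [gan_config()].
#' @return an object of class `gan_model`: list with `generator`,
#'   `discriminator`, a per-step loss `log` data frame, and the config.
#' @export
train_gan <- function(dataset, config = gan_config()) {
  stopifnot(inherits(dataset, "slice_dataset"))
  if (dataset$split != "train")
    stop("GAN training expects the 'train' split (normal-only images)")
  if (length(dataset$images) == 0) stop("empty training dataset")
  N <- nrow(dataset$images[[1]])
  if (N != config$resolution)
    stop("dataset resolution ", N, " does not match config resolution ",
         config$resolution)
  set.seed(config$seed)
  gen <- build_generator(N, config$latent_dim, config$base_channels,
                         config$channel_cap, config$noise_injection)
  disc <- build_discriminator(N, config$base_channels, config$channel_cap)
  st_g <- adam_init()
  st_d <- adam_init()
  B <- config$batch_size
  n_img <- length(dataset$images)
  # decoder reconstructs the 8x-downsampled real image (capped so the target
  # never drops below the decoder's 4x4 minimum output)
  down8 <- min(3L, as.integer(log2(N)) - 2L)
  log_d <- log_g <- log_rec <- numeric(config$steps)

  for (step in seq_len(config$steps)) {
    ## -- discriminator update -----------------------------------------------
    idx <- sample.int(n_img, B, replace = TRUE)
    xr <- .make_batch(dataset$images, idx, config$augment)
    z <- sample_latent(B, config$latent_dim)
    rg <- gen_forward(gen, z, training = TRUE)
    gen <- rg$gen
    xf <- rg$y
    rr <- disc_forward(disc, xr, training = TRUE, with_dec = TRUE)
    disc <- rr$disc
    t8 <- downsample_pow2(xr, down8)
    lrec <- reconstruction_loss(t8, rr$dec)
    rf <- disc_forward(disc, xf, training = TRUE, with_dec = FALSE)
    disc <- rf$disc
    loss_d <- discriminator_loss(rr$logits, rf$logits, lrec)
    g_real <- -as.numeric(1 - rr$logits > 0) / B
    g_fake <- as.numeric(1 + rf$logits > 0) / B
    g_dec <- array(sign(rr$dec - t8) / length(t8), dim(t8))
    br <- disc_backward(disc, rr$caches, g_real, gdec = g_dec, need_gx = FALSE)
    bf <- disc_backward(disc, rf$caches, g_fake, need_gx = FALSE)
    up <- adam_step(disc$mods, add_grads(br$grads, bf$grads), st_d,
                    config$lr, config$betas[1], config$betas[2])
    disc$mods <- up$mods
    st_d <- up$state

    ## -- generator update ---------------------------------------------------
    z2 <- sample_latent(B, config$latent_dim)
    rg2 <- gen_forward(gen, z2, training = TRUE)
    gen <- rg2$gen
    rf2 <- disc_forward(disc, rg2$y, training = TRUE, with_dec = FALSE)
    disc <- rf2$disc
    loss_g <- generator_loss(rf2$logits)
    bd <- disc_backward(disc, rf2$caches, rep(-1 / B, B), need_gx = TRUE)
    bg <- gen_backward(gen, rg2$caches, bd$gx, need_gz = FALSE)
    up <- adam_step(gen$mods, bg$grads, st_g,
                    config$lr, config$betas[1], config$betas[2])
    gen$mods <- up$mods
    st_g <- up$state

    log_d[step] <- loss_d
    log_g[step] <- loss_g
    log_rec[step] <- lrec
    if (!is.null(config$checkpoint_dir) &&
        (step %% config$checkpoint_every == 0 || step == config$steps)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(generator = gen, discriminator = disc, step = step,
                   config = config),
              file.path(config$checkpoint_dir, sprintf("ckpt_%06d.rds", step)))
    }
  }
  structure(list(generator = gen, discriminator = disc,
                 log = data.frame(step = seq_len(config$steps),
                                  loss_d = log_d, loss_g = log_g,
                                  loss_rec = log_rec),
                 config = config), class = "gan_model")
}

#' Generate images from a trained generator
#'
#' @param gen a generator (or a `gan_model`).
#' @param z latent matrix (L x n) or NULL to sample `n` vectors.
#' @param n number of images when `z` is NULL.
#' @param seed optional seed for the latent draw.
#' @return list of unit-scale matrices.
#' @export
generate_images <- function(gen, z = NULL, n = 1, seed = NULL) {
  if (inherits(gen, "gan_model")) gen <- gen$generator
  if (is.null(z)) z <- sample_latent(n, gen$meta$latent_dim, seed = seed)
  r <- gen_forward(gen, z, training = FALSE)
  lapply(seq_len(ncol(z)), function(j) r$y[, , 1L, j])
}
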