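# Encoder training: map images into the generator's latent box so that
# G(E(x)) reconstructs normal inputs; the generator stays frozen throughout.

#' Encoder training / loss configuration
#'
#' Defaults are the full-scale conditions: loss weights w1 = 1 (perceptual)
#' and w2 = 10 (MSE), random-erase probability 0.25, 20,000 steps.
#'
#' @param w1,w2 weights of the perceptual and MSE reconstruction terms.
#' @param backend registered perceptual backend name.
#' @param erase_prob probability of erasing a rectangle from the encoder
#'   input (the reconstruction target stays un-erased).
#' @param erase_frac rectangle side-length range, fractions of image width.
#' @param steps training steps.
#' @param batch_size images per step.
#' @param lr,betas Adam settings.
#' @param base_channels,channel_cap encoder width plan.
#' @param seed RNG seed.
#' @export
encoder_config <- function(w1 = 1, w2 = 10, backend = "random_conv",
                           erase_prob = 0.25, erase_frac = c(0.10, 0.35),
                           steps = 20000, batch_size = 8, lr = 2e-4,
                           betas = c(0.5, 0.999), base_channels = 32,
                           channel_cap = 256, seed = 1) {
  stopifnot(w1 >= 0, w2 >= 0, erase_prob >= 0, erase_prob <= 1, steps >= 1,
            batch_size >= 1, lr > 0)
  structure(list(w1 = w1, w2 = w2, backend = backend, erase_prob = erase_prob,
                 erase_frac = erase_frac, steps = steps,
                 batch_size = batch_size, lr = lr, betas = betas,
                 base_channels = base_channels, channel_cap = channel_cap,
                 seed = seed), class = "encoder_config")
}

# shared reconstruction objective: w1 * perceptual + w2 * MSE
.objective_forward <- function(x, xhat, w1, w2, backend) {
  x <- as_batch_array(x); xhat <- as_batch_array(xhat)
  if (!identical(dim(x), dim(xhat))) stop("shape mismatch")
  pf <- if (w1 > 0) perceptual_forward(xhat, x, backend) else NULL
  lp <- if (is.null(pf)) 0 else pf$value
  lm <- mean((x - xhat)^2)
  list(value = w1 * lp + w2 * lm, percept = lp, mse = lm,
       cache = list(pf = pf, x = x, xhat = xhat, w1 = w1, w2 = w2))
}

# gradient of the objective w.r.t. xhat
.objective_grad <- function(cache) {
  g <- cache$w2 * 2 * (cache$xhat - cache$x) / length(cache$x)
  if (!is.null(cache$pf))
    g <- g + perceptual_backward(cache$pf$cache, scale = cache$w1)$ga
  g
}

#' Encoder reconstruction loss
#'
#' \eqn{w_1 \ell_{percept}(x, \hat x) + w_2 \ell_{MSE}(x, \hat x)} with the
#' weights of `cfg`.  Zero exactly when `xhat == x`.
#'
#' @param x,xhat unit-scale images of equal shape.
#' @param cfg an [encoder_config()] (only `w1`, `w2`, `backend` are used).
#' @return scalar loss.
#' @export
encoder_loss <- function(x, xhat, cfg = encoder_config()) {
  .objective_forward(x, xhat, cfg$w1, cfg$w2, cfg$backend)$value
}

#' Train an encoder against a frozen generator
#'
#' Minimizes the reconstruction objective over randomly erased inputs; the
#' target of the loss is always the un-erased image.  Generator parameters
#' (including batch-norm statistics) are never modified: the generator runs
#' in inference mode and only its input gradient is used.
#'
#' @param dataset a training [slice_dataset()].
#' @param gen a trained generator (or `gan_model`).
#' @param cfg an [encoder_config()].
#' @return object of class `encoder_model` with `encoder`, `log`, `config`.
#' @export
train_encoder <- function(dataset, gen, cfg = encoder_config()) {
  if (inherits(gen, "gan_model")) gen <- gen$generator
  stopifnot(inherits(dataset, "slice_dataset"), inherits(gen, "pseudo_generator"))
  N <- nrow(dataset$images[[1]])
  if (N != gen$meta$resolution)
    stop("dataset resolution ", N, " does not match generator resolution ",
         gen$meta$resolution)
  set.seed(cfg$seed)
  enc <- build_encoder(N, gen$meta$latent_dim, cfg$base_channels,
                       cfg$channel_cap)
  st <- adam_init()
  B <- cfg$batch_size
  n_img <- length(dataset$images)
  losses <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    idx <- sample.int(n_img, B, replace = TRUE)
    x <- .make_batch(dataset$images, idx, aug = NULL)
    xin <- x
    for (j in seq_len(B))
      xin[, , 1L, j] <- random_erase(xin[, , 1L, j], cfg$erase_prob,
                                     cfg$erase_frac)
    re <- seq_forward(enc$mods, xin, training = TRUE)
    enc$mods <- re$mods
    rg <- gen_forward(gen, re$y, training = FALSE)
    ob <- .objective_forward(x, rg$y, cfg$w1, cfg$w2, cfg$backend)
    losses[step] <- ob$value
    gxhat <- .objective_grad(ob$cache)
    gz <- gen_backward(gen, rg$caches, gxhat, need_gz = TRUE)$gz
    be <- seq_backward(enc$mods, re$caches, gz, need_gx = FALSE)
    up <- adam_step(enc$mods, be$grads, st, cfg$lr, cfg$betas[1], cfg$betas[2])
    enc$mods <- up$mods
    st <- up$state
  }
  structure(list(encoder = enc,
                 log = data.frame(step = seq_len(cfg$steps), loss = losses),
                 config = cfg), class = "encoder_model")
}

#' Encode images into latent vectors
#'
#' @param encoder an encoder (or `encoder_model`).
#' @param x matrix or [H,W,1,B] array of unit-scale images.
#' @return L x B latent matrix; every component lies in \[-1,1\].
#' @export
encode <- function(encoder, x) {
  if (inherits(encoder, "encoder_model")) encoder <- encoder$encoder
  x <- as_batch_array(x)
  seq_forward(encoder$mods, x, training = FALSE)$y
}
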