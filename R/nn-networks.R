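# Network builders and their forward/backward orchestration.
#
# Generator: dense stem to a 4x4 map, then log2(N)-2 upsampling blocks
# (nearest-neighbour upsample, 3x3 conv, batch norm, GLU, optional learned
# noise injection), one skip-layer excitation connection from the first block
# to the last when depth allows, and a 3x3 conv + squashing head mapping to a
# single channel in [0,1].  At the paper-scale resolution of 512 this depth
# rule yields 7 blocks, i.e. one block fewer than a full 4->1024 pyramid.
#
# Discriminator: log2(N)-2 strided 4x4 convolutions with spectral
# normalization and leaky ReLU down to a 4x4 feature map, a spectrally
# normalized linear head producing one real-valued logit, and an auxiliary
# decoder head that reconstructs an 8x-downsampled version of (real) inputs
# from the 4x4 features, giving the self-supervised reconstruction loss.
#
# Encoder: log2(N)-1 down-sampling blocks (4x4 stride-2 conv, batch norm,
# GLU) to a 2x2 map, then a linear layer and tanh so the code lands in the
# generator's latent box [-1,1]^L.  At resolution 512 this gives the
# full-scale depth of eight down-sampling blocks.

.check_pow2 <- function(n, lo = 16) {
  if (n < lo || bitwAnd(n, n - 1L) != 0L)
    stop("resolution must be a power of two >= ", lo, ", got ", n)
  invisible(n)
}

.gen_channels <- function(n_blocks, base, cap) {
  c0 <- min(base * 2^n_blocks, cap)
  pmax(base, c0 %/% 2^(0:n_blocks))  # c0, c1, ..., c_nblocks
}

build_generator <- function(resolution, latent_dim = 512, base_channels = 32,
                            channel_cap = 256, noise_injection = TRUE) {
  .check_pow2(resolution)
  n_blocks <- as.integer(log2(resolution)) - 2L
  ch <- .gen_channels(n_blocks, base_channels, channel_cap)
  c0 <- ch[1]
  mods <- list(
    nn_dense(latent_dim, 4 * 4 * 2 * c0),
    nn_reshape(4, 4, 2 * c0),
    nn_bn(2 * c0),
    nn_glu()
  )
  block_bounds <- integer(0)
  cin <- c0
  for (k in seq_len(n_blocks)) {
    ck <- ch[k + 1]
    mods <- c(mods, list(nn_upsample2(), nn_conv(cin, 2 * ck, 3, 1, 1),
                         nn_bn(2 * ck), nn_glu()))
    if (noise_injection) mods <- c(mods, list(nn_noise(ck)))
    block_bounds <- c(block_bounds, length(mods))
    cin <- ck
  }
  use_sle <- n_blocks >= 3L
  sle_idx <- NA_integer_
  if (use_sle) {
    mods <- c(mods, list(nn_sle(ch[2], ch[n_blocks + 1])))
    sle_idx <- length(mods)
  }
  mods <- c(mods, list(nn_conv(cin, 1, 3, 1, 1, gain = 1), nn_tanh01()))
  structure(list(
    mods = mods,
    meta = list(resolution = resolution, latent_dim = latent_dim,
                n_blocks = n_blocks, base_channels = base_channels,
                channel_cap = channel_cap, noise_injection = noise_injection,
                channels = ch, block_bounds = block_bounds,
                sle_idx = sle_idx, tap_end = block_bounds[1])
  ), class = "pseudo_generator")
}

.sle_forward <- function(mod, x_high, x_low) {
  dl <- dim(x_low); hw_l <- dl[1] * dl[2]
  dh <- dim(x_high); hw_h <- dh[1] * dh[2]
  s <- colSums(array(x_low, c(hw_l, dl[3], dl[4]))) / hw_l      # C_low x B
  a <- sigmoid(mod$W %*% s + mod$b)                              # C_high x B
  y <- x_high * rep(as.vector(a), each = hw_h)
  dim(y) <- dh
  list(y = y, cache = list(x_high = x_high, s = s, a = a, dl = dl, dh = dh))
}

.sle_backward <- function(mod, cache, gy) {
  dh <- cache$dh; hw_h <- dh[1] * dh[2]
  dl <- cache$dl; hw_l <- dl[1] * dl[2]
  a <- cache$a
  gx_high <- gy * rep(as.vector(a), each = hw_h)
  dim(gx_high) <- dh
  gA <- colSums(array(gy * cache$x_high, c(hw_h, dh[3], dh[4])))  # C_high x B
  gpre <- gA * a * (1 - a)
  gs <- crossprod(mod$W, gpre)                                    # C_low x B
  gx_low <- rep(as.vector(gs / hw_l), each = hw_l)
  dim(gx_low) <- dl
  list(gx_high = gx_high, gx_low = gx_low,
       grads = list(W = gpre %*% t(cache$s), b = rowSums(gpre)))
}

#' @keywords internal
gen_forward <- function(gen, z, training = TRUE) {
  mods <- gen$mods
  tap_end <- gen$meta$tap_end
  sle_idx <- gen$meta$sle_idx
  caches <- vector("list", length(mods))
  x <- z
  x_low <- NULL
  for (i in seq_along(mods)) {
    if (!is.na(sle_idx) && i == sle_idx) {
      r <- .sle_forward(mods[[i]], x, x_low)
      x <- r$y
      caches[[i]] <- r$cache
    } else {
      r <- mod_forward(mods[[i]], x, training)
      x <- r$y
      caches[[i]] <- r$cache
      mods[[i]] <- r$mod
    }
    if (!is.na(sle_idx) && i == tap_end) x_low <- x
  }
  gen$mods <- mods
  list(y = x, caches = caches, gen = gen)
}

#' @keywords internal
gen_backward <- function(gen, caches, gy, need_gz = TRUE) {
  mods <- gen$mods
  tap_end <- gen$meta$tap_end
  sle_idx <- gen$meta$sle_idx
  grads <- vector("list", length(mods))
  g_low <- NULL
  for (i in rev(seq_along(mods))) {
    if (!is.na(sle_idx) && i == sle_idx) {
      r <- .sle_backward(mods[[i]], caches[[i]], gy)
      gy <- r$gx_high
      g_low <- r$gx_low
      grads[i] <- list(r$grads)
    } else {
      if (!is.null(g_low) && i == tap_end) { gy <- gy + g_low; g_low <- NULL }
      r <- mod_backward(mods[[i]], caches[[i]], gy, need_gx = need_gz || i > 1)
      gy <- r$gx
      grads[i] <- list(r$grads)  # [[<- would drop NULL gradients and misalign
    }
  }
  list(gz = gy, grads = grads)
}

build_discriminator <- function(resolution, base_channels = 32,
                                channel_cap = 256) {
  .check_pow2(resolution)
  n_blocks <- as.integer(log2(resolution)) - 2L
  f <- pmin(base_channels * 2^(seq_len(n_blocks) - 1), channel_cap)
  mods <- list()
  cin <- 1L
  for (k in seq_len(n_blocks)) {
    mods <- c(mods, list(nn_conv(cin, f[k], 4, 2, 1, sn = TRUE), nn_lrelu()))
    cin <- f[k]
  }
  feats_idx <- seq_along(mods)
  mods <- c(mods, list(nn_flatten(), nn_dense(16 * cin, 1, sn = TRUE)))
  head_idx <- setdiff(seq_along(mods), feats_idx)
  n_up <- max(0L, as.integer(log2(resolution)) - 5L)
  dm <- max(4L, cin %/% 2L)
  dec <- list(nn_conv(cin, dm, 3, 1, 1), nn_lrelu())
  cdec <- dm
  for (j in seq_len(n_up)) {
    cn <- max(4L, cdec %/% 2L)
    dec <- c(dec, list(nn_upsample2(), nn_conv(cdec, cn, 3, 1, 1), nn_lrelu()))
    cdec <- cn
  }
  dec <- c(dec, list(nn_conv(cdec, 1, 3, 1, 1, gain = 1), nn_sigmoid()))
  dec_idx <- length(mods) + seq_along(dec)
  mods <- c(mods, dec)
  structure(list(
    mods = mods,
    meta = list(resolution = resolution, n_blocks = n_blocks,
                base_channels = base_channels, channel_cap = channel_cap,
                feats_idx = feats_idx, head_idx = head_idx, dec_idx = dec_idx)
  ), class = "pseudo_discriminator")
}

.run_sub <- function(mods, idx, x, training) {
  r <- seq_forward(mods[idx], x, training)
  list(y = r$y, caches = r$caches, mods = replace(mods, idx, r$mods))
}

#' @keywords internal
disc_forward <- function(disc, x, training = TRUE, with_dec = FALSE) {
  m <- disc$meta
  rf <- .run_sub(disc$mods, m$feats_idx, x, training)
  f4 <- rf$y
  rh <- .run_sub(rf$mods, m$head_idx, f4, training)
  dec <- NULL
  dec_caches <- NULL
  mods <- rh$mods
  if (with_dec) {
    rd <- .run_sub(mods, m$dec_idx, f4, training)
    dec <- rd$y
    dec_caches <- rd$caches
    mods <- rd$mods
  }
  disc$mods <- mods
  list(logits = as.numeric(rh$y), dec = dec,
       caches = list(feats = rf$caches, head = rh$caches, dec = dec_caches),
       disc = disc)
}

#' @keywords internal
disc_backward <- function(disc, caches, glogits, gdec = NULL, need_gx = FALSE) {
  m <- disc$meta
  B <- length(glogits)
  grads <- vector("list", length(disc$mods))
  rh <- seq_backward(disc$mods[m$head_idx], caches$head,
                     matrix(glogits, 1, B), need_gx = TRUE)
  grads[m$head_idx] <- rh$grads
  gf4 <- rh$gx
  if (!is.null(gdec)) {
    rd <- seq_backward(disc$mods[m$dec_idx], caches$dec, gdec, need_gx = TRUE)
    grads[m$dec_idx] <- rd$grads
    gf4 <- gf4 + rd$gx
  }
  rf <- seq_backward(disc$mods[m$feats_idx], caches$feats, gf4,
                     need_gx = need_gx)
  grads[m$feats_idx] <- rf$grads
  list(gx = rf$gx, grads = grads)
}

build_encoder <- function(resolution, latent_dim = 512, base_channels = 32,
                          channel_cap = 256) {
  .check_pow2(resolution)
  n_blocks <- as.integer(log2(resolution)) - 1L
  e <- pmin(base_channels * 2^(seq_len(n_blocks) - 1), channel_cap)
  mods <- list()
  cin <- 1L
  for (k in seq_len(n_blocks)) {
    mods <- c(mods, list(nn_conv(cin, 2 * e[k], 4, 2, 1), nn_bn(2 * e[k]),
                         nn_glu()))
    cin <- e[k]
  }
  mods <- c(mods, list(nn_flatten(), nn_dense(4 * cin, latent_dim, gain = 1),
                       nn_tanh()))
  structure(list(
    mods = mods,
    meta = list(resolution = resolution, latent_dim = latent_dim,
                n_blocks = n_blocks, base_channels = base_channels,
                channel_cap = channel_cap)
  ), class = "pseudo_encoder")
}

# deterministic fingerprint of a parameter set (used to assert frozen networks)
params_checksum <- function(net) {
  digest::digest(lapply(net$mods, function(m)
    m[intersect(names(m), c("W", "b", "gamma", "beta", "nw"))]))
}
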