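# Network machinery: analytic gradients against finite differences, latent
# box enforcement, architecture depth rules.

numgrad_z <- function(gen, z, tgt) {
  f <- function(zv) {
    y <- pseudohealthy:::gen_forward(gen, matrix(zv, length(zv), 1),
                                     training = FALSE)$y
    sum((y - tgt)^2)
  }
  vapply(seq_along(z), function(i) {
    zp <- z; zp[i] <- zp[i] + 1e-5
    zm <- z; zm[i] <- zm[i] - 1e-5
    (f(zp) - f(zm)) / 2e-5
  }, numeric(1))
}

test_that("backpropagated latent gradients match finite differences", {
  set.seed(1)
  for (N in c(16, 32)) {
    gen <- pseudohealthy:::build_generator(N, 6, base_channels = 4,
                                           channel_cap = 16)
    z <- matrix(runif(6, -1, 1), 6, 1)
    tgt <- array(runif(N * N), c(N, N, 1, 1))
    r <- pseudohealthy:::gen_forward(gen, z, training = FALSE)
    gz <- pseudohealthy:::gen_backward(gen, r$caches, 2 * (r$y - tgt),
                                       need_gz = TRUE)$gz
    ng <- numgrad_z(gen, z, tgt)
    expect_lt(max(abs(as.vector(gz) - ng)) / max(abs(ng)), 1e-6)
  }
})

test_that("discriminator input gradients match finite differences", {
  set.seed(2)
  N <- 16
  disc <- pseudohealthy:::build_discriminator(N, base_channels = 4,
                                              channel_cap = 16)
  x <- array(runif(N * N), c(N, N, 1, 1))
  rd <- pseudohealthy:::disc_forward(disc, x, training = FALSE)
  bd <- pseudohealthy:::disc_backward(disc, rd$caches, 1, need_gx = TRUE)
  f <- function(xv) {
    xx <- array(xv, c(N, N, 1, 1))
    pseudohealthy:::disc_forward(disc, xx, training = FALSE)$logits
  }
  idx <- sample(N * N, 25)
  ng <- vapply(idx, function(i) {
    xp <- as.vector(x); xp[i] <- xp[i] + 1e-5
    xm <- as.vector(x); xm[i] <- xm[i] - 1e-5
    (f(xp) - f(xm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(as.vector(bd$gx)[idx] - ng)) / max(abs(ng)), 1e-6)
})

test_that("depth rules instantiate the full-scale architecture counts", {
  # at 512: 7 generator upsampling blocks (one fewer than a 4->1024 pyramid)
  g <- pseudohealthy:::build_generator(512, 8, base_channels = 4,
                                       channel_cap = 8)
  expect_equal(g$meta$n_blocks, 7L)
  # encoder at 512: eight down-sampling blocks
  e <- pseudohealthy:::build_encoder(512, 8, base_channels = 4,
                                     channel_cap = 8)
  expect_equal(e$meta$n_blocks, 8L)
  expect_error(pseudohealthy:::build_generator(48, 8), "power of two")
})

test_that("encoder outputs always lie in the latent box", {
  set.seed(3)
  enc <- pseudohealthy:::build_encoder(32, 16, base_channels = 4,
                                       channel_cap = 16)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  z <- pseudohealthy:::seq_forward(enc$mods, x, training = FALSE)$y
  expect_equal(dim(z), c(16, 3))
  expect_true(all(abs(z) <= 1))
})
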