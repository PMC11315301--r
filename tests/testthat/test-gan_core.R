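# GAN core: loss formulas, latent sampling, augmentation, spectral norm,
# and a short training smoke run.

test_that("generator loss is the negative mean logit", {
  expect_equal(generator_loss(c(1, 3)), -2)
  expect_equal(generator_loss(0), 0)
  set.seed(1)
  lg <- rnorm(50)
  expect_equal(generator_loss(lg), generator_loss(sample(lg)))
})

test_that("discriminator hinge loss matches its definition", {
  expect_equal(discriminator_loss(2, -3, 0), 0)       # both hinges inactive
  expect_equal(discriminator_loss(0, 0, 0), 2)
  expect_equal(discriminator_loss(0.5, -0.5, 0.25), 1.25)
  set.seed(2)
  for (i in 1:20) {
    r <- rnorm(8); f <- rnorm(8); rec <- runif(1)
    manual <- mean(sapply(r, function(v) max(0, 1 - v))) +
      mean(sapply(f, function(v) max(0, 1 + v))) + rec
    expect_equal(discriminator_loss(r, f, rec), manual)
    expect_gte(discriminator_loss(r, f, rec), 0)
  }
})

test_that("auxiliary reconstruction loss is a mean absolute error", {
  x <- matrix(runif(16), 4, 4)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, x + 0.1), 0.1)
  expect_equal(reconstruction_loss(x, x - 0.1), 0.1)   # symmetric in sign
  expect_error(reconstruction_loss(x, matrix(0, 2, 2)), "shape mismatch")
})

test_that("latent sampling covers the box uniformly and is reproducible", {
  z <- sample_latent(1000, 100, seed = 3)
  expect_equal(dim(z), c(100, 1000))
  expect_true(all(z >= -1 & z <= 1))
  # mean of U[-1,1] is 0 with se = 1/sqrt(3n)
  se <- 1 / sqrt(3 * length(z))
  expect_lt(abs(mean(z)), 3 * se)
  expect_identical(z, sample_latent(1000, 100, seed = 3))
})

test_that("augmentation preserves unit scale and degenerates to identity", {
  img <- matrix(runif(64), 8, 8)
  id_cfg <- augment_config(mirror_prob = 0, contrast_range = c(1, 1),
                           translate_frac = 0)
  expect_identical(augment(img, id_cfg), img)
  # mirroring twice restores the original
  m1 <- img[, 8:1]
  expect_identical(m1[, 8:1], img)
  # translation moves a lit pixel to the expected coordinate
  pt <- matrix(0, 8, 8); pt[4, 5] <- 1
  sh <- pseudohealthy:::shift_image(pt, 2, -1)
  expect_equal(which(sh == 1, arr.ind = TRUE)[1, ], c(row = 6, col = 4))
  expect_equal(sum(sh), 1)
  # random augmentation keeps values in [0,1]
  set.seed(4)
  for (i in 1:20) {
    a <- augment(img, augment_config())
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("spectral normalization drives the top singular value to one", {
  set.seed(5)
  for (build in list(function() pseudohealthy:::nn_conv(3, 4, 3, 1, 1, sn = TRUE),
                     function() pseudohealthy:::nn_dense(20, 6, sn = TRUE))) {
    m <- build()
    m$W <- m$W * 7   # far from normalized
    for (i in 1:100) m <- pseudohealthy:::.sn_apply(m, TRUE)$mod
    Ws <- pseudohealthy:::.sn_apply(m, FALSE)$Ws
    expect_equal(svd(Ws)$d[1], 1, tolerance = 1e-6)
  }
})

test_that("a short training run completes with finite losses and right shapes", {
  ds <- fixture_phantoms()
  cfg <- gan_config(resolution = 32, latent_dim = 16, steps = 60,
                    base_channels = 4, channel_cap = 32, seed = 3)
  m <- train_gan(ds, cfg)
  expect_true(all(is.finite(as.matrix(m$log[, c("loss_d", "loss_g", "loss_rec")]))))
  imgs <- generate_images(m, n = 2, seed = 1)
  expect_equal(dim(imgs[[1]]), c(32, 32))
  expect_true(all(imgs[[1]] >= 0 & imgs[[1]] <= 1))
  # a 16x16 configuration produces 16x16 output
  g16 <- pseudohealthy:::build_generator(16, 8, 4, 16)
  y <- pseudohealthy:::gen_forward(g16, matrix(0, 8, 1), training = FALSE)$y
  expect_equal(dim(y)[1:2], c(16, 16))
})

test_that("identical seeds reproduce identical training trajectories", {
  ds <- fixture_phantoms()
  cfg <- gan_config(resolution = 32, latent_dim = 16, steps = 40,
                    base_channels = 4, channel_cap = 32, seed = 11)
  m1 <- train_gan(ds, cfg)
  m2 <- train_gan(ds, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$generator$mods, m2$generator$mods)
})

test_that("training rejects invalid datasets", {
  ds <- fixture_phantoms()
  cfg <- gan_config(resolution = 64, latent_dim = 16, steps = 5,
                    base_channels = 4)
  expect_error(train_gan(ds, cfg), "resolution")
  val <- phantom_with_lesions(phantom_spec(resolution = 32, seed = 4), 2,
                              split = "validation")
  expect_error(train_gan(val, gan_config(resolution = 32, steps = 5)),
               "train")
})
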