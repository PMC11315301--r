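# Residual maps, thresholding, closing, voting, multi-slice filtering.

test_that("residual functions implement |.| and max(., 0) on the byte scale", {
  x <- matrix(c(0.1, 0.5), 1, 2)
  xh <- matrix(c(0.1 + 5 / 255, 0.5 - 10 / 255), 1, 2)  # diffs -5, +10 byte
  ra <- residual_map(x, xh, "abs")
  rp <- residual_map(x, xh, "positive_part")
  expect_equal(as.vector(ra), c(5, 10), tolerance = 1e-9)
  expect_equal(as.vector(rp), c(0, 10), tolerance = 1e-9)
  expect_equal(unclass(residual_map(x, x, "abs")), matrix(0, 1, 2),
               ignore_attr = TRUE)
  set.seed(1)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_true(all(residual_map(a, b, "positive_part") <= residual_map(a, b, "abs")))
  expect_error(residual_map(a, matrix(0, 4, 4)), "shape")
})

test_that("thresholding is strict and monotone", {
  r <- matrix(c(30, 36, 40, 0), 2, 2)
  expect_equal(as.vector(threshold_mask(r, 36)), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(threshold_mask(r, 0), r > 0)
  expect_false(any(threshold_mask(r, max(r))))
  set.seed(2)
  rr <- matrix(runif(256, 0, 255), 16, 16)
  counts <- sapply(seq(0, 255, by = 5), function(t) sum(threshold_mask(rr, t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("closing matches the brute-force dilate-erode oracle and its laws", {
  set.seed(3)
  for (i in 1:25) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    r <- sample(1:2, 1)
    cl <- close_mask(m, r)
    expect_identical(cl, oracle_closing(m, r))
    expect_true(all(cl[m]))                       # extensive
    expect_identical(close_mask(cl, r), cl)       # idempotent
  }
  expect_identical(close_mask(matrix(TRUE, 3, 3), 0), matrix(TRUE, 3, 3))
  # a one-pixel gap between two lit pixels is bridged
  g <- matrix(FALSE, 7, 7); g[4, 3] <- TRUE; g[4, 5] <- TRUE
  expect_true(close_mask(g, 1)[4, 4])
})

test_that("majority vote counts per pixel and rejects even ensembles", {
  m1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  m3 <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  v <- majority_vote(list(m1, m2, m3))
  expect_equal(as.vector(v), c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(majority_vote(list(m1, m1, m1)), m1)
  expect_error(majority_vote(list(m1, m2)), "odd")
  set.seed(4)
  for (i in 1:20) {
    ms <- replicate(5, matrix(runif(256) < 0.5, 16, 16), simplify = FALSE)
    counts <- Reduce(`+`, ms)
    expect_identical(majority_vote(ms), counts >= 3)
    expect_identical(majority_vote(ms), majority_vote(rev(ms)))
  }
  # voting cannot invent pixels absent from every member
  ms <- replicate(3, matrix(runif(64) < 0.2, 8, 8), simplify = FALSE)
  expect_true(all(Reduce(`|`, ms)[majority_vote(ms)]))
})

test_that("multi-slice filtering removes small or short 3D components", {
  # single voxel, min_size 2 -> removed
  masks <- replicate(3, matrix(FALSE, 6, 6), simplify = FALSE)
  masks[[2]][3, 3] <- TRUE
  out <- multi_slice_filter(masks, min_size = 2)
  expect_false(any(unlist(out)))
  # identity parameters change nothing
  set.seed(5)
  ms <- replicate(4, matrix(runif(64) < 0.3, 8, 8), simplify = FALSE)
  expect_identical(multi_slice_filter(ms, 1, 1), ms)
  # component sizes match a brute-force flood fill
  stack <- array(FALSE, c(8, 8, 4))
  for (s in 1:4) stack[, , s] <- ms[[s]]
  lab <- oracle_label3d(stack)
  keep_sizes <- table(lab[lab > 0])
  filtered <- multi_slice_filter(ms, min_size = 4)
  kept <- array(FALSE, dim(stack))
  for (s in 1:4) kept[, , s] <- filtered[[s]]
  manual <- lab > 0 & array(lab %in% as.integer(names(keep_sizes)[keep_sizes >= 4]),
                            dim(lab))
  expect_identical(kept, manual)
  # span filter: a component on one slice only is dropped at min_span 2
  one <- replicate(3, matrix(FALSE, 5, 5), simplify = FALSE)
  one[[1]][2:4, 2:4] <- TRUE
  expect_false(any(unlist(multi_slice_filter(one, 1, 2))))
})

test_that("detect composes residual, threshold, closing and vote", {
  gan <- fixture_tiny_gan()
  models <- list(gan, gan, gan)
  spec <- phantom_spec(resolution = 32, seed = 21)
  les <- phantom_with_lesions(spec, 1)
  x <- les$images[[1]]
  cfg <- anomaly_config(residual_kind = "positive_part", threshold = 30,
                        closing_radius = 1)
  rcfg <- fixture_restore_cfg(40)
  out <- detect(x, models, cfg, mode = "restore", restore_cfg = rcfg)
  # manual composition of the stages reproduces the pipeline exactly
  xh <- reconstruct_image(unclass(x), gan, "restore", rcfg)
  r <- residual_map(unclass(x), xh, "positive_part")
  manual <- close_mask(threshold_mask(r, 30), 1)
  expect_identical(out$per_model_masks[[1]], manual)
  expect_identical(out$mask, majority_vote(out$per_model_masks))
  expect_identical(out$mask, manual)  # identical members vote unanimously
  expect_equal(out$mean_reconstruction, xh, tolerance = 1e-12)
  # an input equal to its reconstruction yields an empty mask
  x0 <- generate_images(gan, z = matrix(0, 64, 1))[[1]]
  same <- detect(x0, models, cfg, mode = "restore",
                 restore_cfg = restoration_config(steps = 0))
  expect_false(any(same$mask))
})

test_that("encoder-mode detection demands a trained encoder", {
  gan <- fixture_tiny_gan()
  expect_error(reconstruct_image(fixture_phantoms()$images[[1]], gan, "encoder"),
               "no trained encoder")
})
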