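# Evaluation metrics: Dice, pooled ROC, operating-point sweep, error stats.

test_that("dice matches its closed form on canonical cases", {
  m <- function(v) matrix(v, 2, 2)
  a <- m(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, m(c(FALSE, FALSE, TRUE, TRUE))), 0)
  p <- matrix(FALSE, 4, 4); p[1:2, 1:2] <- TRUE      # 4 pixels
  r <- matrix(FALSE, 4, 4); r[2:3, 1:2] <- TRUE      # 4 pixels, overlap 2
  expect_equal(dice(p, r), 0.5)
  expect_equal(dice(p, r), dice(r, p))               # symmetric
  both <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dice(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("pooled ROC agrees with an exhaustive confusion-matrix recomputation", {
  set.seed(1)
  residuals <- replicate(3, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  refs <- replicate(3, matrix(runif(64) < 0.3, 8, 8), simplify = FALSE)
  th <- seq(0, 260, by = 20)
  roc <- roc_curve(residuals, refs, th)
  pooled_r <- unlist(residuals)
  pooled_y <- unlist(refs)
  for (k in seq_along(th)) {
    pred <- pooled_r > th[k]
    expect_equal(roc$tpr[k], sum(pred & pooled_y) / sum(pooled_y))
    expect_equal(roc$fpr[k], sum(pred & !pooled_y) / sum(!pooled_y))
  }
  # endpoints: below the minimum everything is positive, above the max nothing
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(1, 1))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(0, 0))
  expect_error(roc_curve(residuals, replicate(3, matrix(FALSE, 8, 8),
                                              simplify = FALSE), th),
               "degenerate")
})

test_that("ROC rates are monotone non-increasing in the threshold", {
  set.seed(2)
  for (i in 1:10) {
    residuals <- replicate(2, matrix(runif(256, 0, 255), 16, 16), simplify = FALSE)
    refs <- replicate(2, matrix(runif(256) < 0.4, 16, 16), simplify = FALSE)
    roc <- roc_curve(residuals, refs, seq(0, 255, by = 15))
    expect_true(all(diff(roc$tpr) <= 1e-12))
    expect_true(all(diff(roc$fpr) <= 1e-12))
    expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
    auc <- roc_auc(roc)
    expect_true(auc >= 0 && auc <= 1)
  }
})

test_that("the operating-point sweep finds a constructed optimum", {
  ref <- matrix(FALSE, 8, 8); ref[3:6, 3:6] <- TRUE
  res <- matrix(0, 8, 8)
  res[ref] <- 20          # lesion residual just above t = 10
  res[1, 1] <- 200        # an outlier false positive above every t
  res[1, 2] <- 8          # extra false positive that only t >= 10 excludes
  sw <- sweep_operating_point(list(res), list(ref), thresholds = c(5, 10, 50, 250))
  expect_equal(sw$threshold, 10)   # t in [10, 20) keeps the lesion, drops the 8
  expect_true(sw$threshold %in% sw$sweep$threshold)
  expect_equal(nrow(sw$sweep), 4)
  one <- sweep_operating_point(list(res), list(ref), thresholds = 7)
  expect_equal(one$threshold, 7)
  # ties resolve to the smallest threshold
  flat <- sweep_operating_point(list(matrix(0, 4, 4)),
                                list(matrix(FALSE, 4, 4) | diag(4) > 0),
                                thresholds = c(1, 2, 3))
  expect_equal(flat$threshold, 1)
})

test_that("reconstruction statistics match direct per-pixel recomputation", {
  x <- list(matrix(0.5, 4, 4))
  xh <- list(matrix(0.4, 4, 4))
  st <- reconstruction_stats(x, xh)
  expect_equal(st$rmse, 0.1)
  expect_equal(st$mean_abs, 0.1)
  expect_equal(st$sd_abs, 0)
  expect_equal(st$p90_abs, 0.1)
  expect_equal(reconstruction_stats(x, x)$rmse, 0)
  set.seed(3)
  xs <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
  xhs <- replicate(4, matrix(runif(64), 8, 8), simplify = FALSE)
  gr <- c("normal", "normal", "abnormal", "abnormal")
  st <- reconstruction_stats(xs, xhs, gr)
  for (g in c("normal", "abnormal")) {
    d <- abs(unlist(xs[gr == g]) - unlist(xhs[gr == g]))
    row <- st[st$group == g, ]
    expect_equal(row$rmse, sqrt(mean(d^2)))
    expect_equal(row$mean_abs, mean(d))
    expect_equal(row$sd_abs, sd(d))
    expect_equal(row$p90_abs, as.numeric(quantile(d, 0.9)))
  }
})

test_that("lesion detection uses a strict Dice cutoff", {
  expect_equal(detection_rate(c(0.5, 0.05)), 0.5)
  expect_equal(detection_rate(c(0.2, 0.9, 0.11)), 1)
  expect_equal(detection_rate(c(0.1, 0.1)), 0)   # exactly at cutoff: missed
})

test_that("per-lesion dice isolates each reference component", {
  ref <- matrix(FALSE, 16, 16)
  ref[2:4, 2:4] <- TRUE        # lesion A (9 px)
  ref[10:13, 10:13] <- TRUE    # lesion B (16 px)
  pred <- matrix(FALSE, 16, 16)
  pred[2:4, 2:4] <- TRUE       # A found perfectly
  ld <- sort(lesion_dice(pred, ref))
  expect_length(ld, 2)
  expect_equal(ld, c(0, 1))
  # false positives far from a lesion do not dilute its score
  pred[16, 16] <- TRUE
  expect_equal(sort(lesion_dice(pred, ref)), c(0, 1))
  expect_length(lesion_dice(pred, matrix(FALSE, 16, 16)), 0)
})
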