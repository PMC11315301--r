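# Evaluation machinery: Dice, pixel-pooled ROC curves, operating-point
# sweeps, reconstruction-error statistics, and lesion-level detection.

#' Dice overlap between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}.  When both masks are empty the score is
#' defined as 1 (perfect agreement on "nothing to segment"); this case only
#' arises on normal images and is flagged via the `both_empty` attribute.
#'
#' @param pred,ref logical matrices of equal shape.
#' @return scalar in \[0,1\].
#' @export
dice <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("mask shape mismatch")
  np <- sum(pred); nr <- sum(ref)
  if (np + nr == 0) return(structure(1, both_empty = TRUE))
  2 * sum(pred & ref) / (np + nr)
}

# voted binary mask of one image at threshold t; `res` is a residual matrix
# or a list of per-model residual matrices
.mask_at <- function(res, t, closing_radius = 0) {
  if (is.list(res)) {
    majority_vote(lapply(res, function(r)
      close_mask(threshold_mask(r, t), closing_radius)))
  } else {
    close_mask(threshold_mask(res, t), closing_radius)
  }
}

#' Pixel-pooled ROC curve over a residual dataset
#'
#' Pixels are pooled across all images; for each threshold the pooled
#' true-positive and false-positive rates are computed.  For single-model
#' residuals a pixel is predicted positive when its residual exceeds the
#' threshold; for per-model residual lists, when the ensemble majority vote
#' at that threshold lights the pixel.
#'
#' @param residuals list of residual matrices (or lists of per-model
#'   residual matrices).
#' @param refs list of reference logical masks, parallel to `residuals`.
#' @param thresholds numeric vector of thresholds (byte scale by default).
#' @param closing_radius radius used when masks are voted (default 0: pure
#'   thresholding, so rates are exact functions of the pooled residuals).
#' @return data frame (threshold, fpr, tpr) of class `roc_curve`.
#' @export
roc_curve <- function(residuals, refs, thresholds = 0:255,
                      closing_radius = 0) {
  stopifnot(length(residuals) == length(refs), length(thresholds) >= 1)
  pos <- sum(vapply(refs, sum, numeric(1)))
  neg <- sum(vapply(refs, length, numeric(1))) - pos
  if (pos == 0 || neg == 0)
    stop("degenerate pooled set: need at least one positive and one negative pixel")
  tpr <- fpr <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    tp <- fp <- 0
    for (i in seq_along(residuals)) {
      m <- .mask_at(residuals[[i]], thresholds[k], closing_radius)
      tp <- tp + sum(m & refs[[i]])
      fp <- fp + sum(m & !refs[[i]])
    }
    tpr[k] <- tp / pos
    fpr[k] <- fp / neg
  }
  structure(data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' Area under a pixel-pooled ROC curve
#'
#' Trapezoidal area over the curve points augmented with the (0,0) and (1,1)
#' endpoints.
#'
#' @param roc a [roc_curve()] result.
#' @export
roc_auc <- function(roc) {
  x <- c(0, rev(roc$fpr), 1)
  y <- c(0, rev(roc$tpr), 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Choose the operating threshold on a validation split
#'
#' Evaluates the per-image Dice of the (optionally voted and closed) masks at
#' every threshold of the grid and returns the threshold maximizing the
#' criterion (default: median Dice), with ties resolved toward the smallest
#' threshold, plus the full sweep table.
#'
#' @param residuals list of residual matrices or per-model residual lists.
#' @param refs list of reference logical masks.
#' @param thresholds threshold grid (byte-scale integers by default).
#' @param criterion "median" or "mean" Dice.
#' @param closing_radius closing radius applied before voting.
#' @return list with `threshold` (t*) and `sweep` (data frame threshold,
#'   median_dice, mean_dice).
#' @export
sweep_operating_point <- function(residuals, refs, thresholds = 0:255,
                                  criterion = c("median", "mean"),
                                  closing_radius = 0) {
  criterion <- match.arg(criterion)
  stopifnot(length(residuals) >= 1, length(residuals) == length(refs),
            length(thresholds) >= 1)
  med <- mea <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    d <- vapply(seq_along(residuals), function(i)
      as.numeric(dice(.mask_at(residuals[[i]], thresholds[k], closing_radius),
                      refs[[i]])), numeric(1))
    med[k] <- stats::median(d)
    mea[k] <- mean(d)
  }
  score <- if (criterion == "median") med else mea
  best <- which.max(score)  # which.max takes the first maximum: smallest t
  list(threshold = thresholds[best],
       sweep = data.frame(threshold = thresholds, median_dice = med,
                          mean_dice = mea))
}

#' Reconstruction-error statistics
#'
#' For unit-scale (input, reconstruction) pairs, reports the RMSE, the mean
#' and standard deviation of the absolute pixel difference, and the 90th
#' percentile of the pixel difference, pooled over all pixels of each group.
#'
#' @param x,xhat parallel lists of unit-scale matrices.
#' @param groups character vector parallel to the pairs (e.g. "normal" /
#'   "abnormal"); a single group is used when omitted.
#' @return data frame with one row per group: rmse, mean_abs, sd_abs, p90_abs.
#' @export
reconstruction_stats <- function(x, xhat, groups = NULL) {
  stopifnot(length(x) == length(xhat), length(x) >= 1)
  if (is.null(groups)) groups <- rep("all", length(x))
  stopifnot(length(groups) == length(x))
  out <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    d <- unlist(lapply(idx, function(i) {
      if (!identical(dim(x[[i]]), dim(xhat[[i]]))) stop("shape mismatch")
      abs(as.numeric(unclass(x[[i]])) - as.numeric(unclass(xhat[[i]])))
    }))
    data.frame(group = g, rmse = sqrt(mean(d^2)), mean_abs = mean(d),
               sd_abs = stats::sd(d),
               p90_abs = as.numeric(stats::quantile(d, 0.9)))
  })
  do.call(rbind, out)
}

#' Lesion detection rate
#'
#' Fraction of lesions whose Dice strictly exceeds the cutoff (a lesion with
#' Dice exactly at the cutoff counts as missed).
#'
#' @param dice_values numeric vector of per-lesion Dice scores.
#' @param cutoff detection cutoff (default 0.1).
#' @export
detection_rate <- function(dice_values, cutoff = 0.1) {
  stopifnot(length(dice_values) >= 1)
  mean(dice_values > cutoff)
}

#' Per-lesion Dice scores
#'
#' Each connected component of the reference mask is scored against the
#' prediction restricted to a dilated neighbourhood of that component, so
#' false positives elsewhere in the image do not dilute a lesion's score.
#'
#' @param pred predicted logical mask.
#' @param ref reference logical mask.
#' @param dilate_radius neighbourhood radius in pixels.
#' @return numeric vector, one Dice value per reference lesion (empty when
#'   the reference has no lesion).
#' @export
lesion_dice <- function(pred, ref, dilate_radius = 3) {
  if (!identical(dim(pred), dim(ref))) stop("mask shape mismatch")
  stack <- array(ref, c(dim(ref), 1L))
  lab <- cpp_label_components_3d(stack)[, , 1L]
  nlab <- max(lab)
  if (nlab == 0L) return(numeric(0))
  vapply(seq_len(nlab), function(l) {
    comp <- lab == l
    neigh <- EBImage::dilate(comp * 1,
                             EBImage::makeBrush(2L * dilate_radius + 1L,
                                                "disc")) > 0.5
    dim(neigh) <- dim(ref)
    as.numeric(dice(pred & neigh, comp))
  }, numeric(1))
}
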