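# From (input, reconstruction) pairs to binary anomaly masks: residual
# function, byte-scale thresholding, morphological closing, majority-vote
# ensembling, and multi-slice connected-component filtering.

#' Anomaly-map configuration
#'
#' Residuals are expressed in byte-scale intensity units (0-255) so the
#' operating threshold is meaningful on the scale on which it is reported;
#' the default operating point is t = 36.  The closing structuring element is
#' a disk of radius 2 pixels at resolution 512, scaled proportionally at
#' other resolutions (NULL requests that automatic scaling).
#'
#' @param residual_kind "abs" (any deviation) or "positive_part"
#'   (brighter-than-reconstruction deviations, e.g. acute hemorrhage).
#' @param threshold residual threshold in byte-scale units.
#' @param closing_radius disk radius in pixels, or NULL for resolution-scaled.
#' @param ensemble_size number of models voting (odd).
#' @param min_component_size,min_slice_span multi-slice component filter.
#' @export
anomaly_config <- function(residual_kind = c("abs", "positive_part"),
                           threshold = 36, closing_radius = NULL,
                           ensemble_size = 3, min_component_size = 1,
                           min_slice_span = 1) {
  residual_kind <- match.arg(residual_kind)
  stopifnot(threshold >= 0, ensemble_size %% 2 == 1,
            min_component_size >= 1, min_slice_span >= 1)
  structure(list(residual_kind = residual_kind, threshold = threshold,
                 closing_radius = closing_radius,
                 ensemble_size = as.integer(ensemble_size),
                 min_component_size = min_component_size,
                 min_slice_span = min_slice_span), class = "anomaly_config")
}

default_closing_radius <- function(resolution) {
  as.integer(round(2 * resolution / 512))
}

#' Residual map between an image and its reconstruction
#'
#' `abs` gives |x - xhat| elementwise; `positive_part` gives max(x - xhat, 0).
#' With `scale = "byte"` the unit-scale difference is multiplied by 255 so
#' thresholds are in display-intensity units.
#'
#' @param x,xhat unit-scale matrices of equal shape.
#' @param kind residual function.
#' @param scale "byte" (default) or "unit".
#' @return non-negative matrix.
#' @export
residual_map <- function(x, xhat, kind = c("abs", "positive_part"),
                         scale = c("byte", "unit")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (!identical(dim(x), dim(xhat)))
    stop("shape mismatch between image and reconstruction")
  d <- unclass(x) - unclass(xhat)
  r <- if (kind == "abs") abs(d) else pmax(d, 0)
  if (scale == "byte") r <- 255 * r
  attr(r, "scale") <- scale
  r
}

#' Threshold a residual map into a binary mask
#'
#' Strict comparison: a pixel is anomalous iff its residual exceeds `t`.
#'
#' @param r non-negative residual matrix.
#' @param t threshold (same units as `r`).
#' @return logical matrix.
#' @export
threshold_mask <- function(r, t) {
  stopifnot(t >= 0)
  unclass(r) > t
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk structuring element; fills small
#' gaps and holes.  The result always contains the input, and the operation
#' is idempotent.  Radius 0 is the identity.
#'
#' @param m logical matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
close_mask <- function(m, radius) {
  stopifnot(is.matrix(m), radius >= 0)
  if (radius == 0 || !any(m)) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
  out <- EBImage::closing(m * 1, brush) > 0.5
  dim(out) <- dim(m)
  out
}

#' Per-pixel majority vote over an odd ensemble of masks
#'
#' @param masks list of equally shaped logical matrices, odd length.
#' @return logical matrix; a pixel is lit iff lit in more than half the masks.
#' @export
majority_vote <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  if (length(masks) %% 2 == 0)
    stop("majority vote needs an odd number of masks (no tie-breaking rule)")
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mask shape mismatch")
  Reduce(`+`, masks) > length(masks) / 2
}

#' Filter small or short 3D components across a slice stack
#'
#' Connected components are computed with 26-connectivity across the ordered
#' slice stack; components with fewer than `min_size` voxels or spanning
#' fewer than `min_span` slices are removed, surviving components are kept
#' unchanged.
#'
#' @param masks ordered list of equally shaped logical slice masks.
#' @param min_size minimum component voxel count.
#' @param min_span minimum number of slices a component must touch.
#' @return list of filtered logical masks.
#' @export
multi_slice_filter <- function(masks, min_size = 1, min_span = 1) {
  stopifnot(is.list(masks), length(masks) >= 1)
  d <- dim(masks[[1]])
  stack <- array(FALSE, c(d, length(masks)))
  for (s in seq_along(masks)) stack[, , s] <- masks[[s]]
  lab <- cpp_label_components_3d(stack)
  if (max(lab) == 0L) return(masks)
  keep <- logical(max(lab))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  slice_of <- rep(seq_along(masks), each = prod(d))
  spans <- vapply(seq_len(max(lab)), function(l)
    length(unique(slice_of[lab == l])), integer(1))
  keep <- sizes >= min_size & spans >= min_span
  ok <- array(lab > 0 & keep[pmax(lab, 1L)], dim(lab))
  lapply(seq_along(masks), function(s) {
    m <- ok[, , s]
    dim(m) <- d
    m
  })
}

#' End-to-end anomaly detection for one slice
#'
#' For every ensemble member: reconstruct the pseudo-healthy image, compute
#' the residual, threshold at the operating point and close the mask; the
#' per-model binary masks are then combined by per-pixel majority vote.  The
#' averaged reconstruction is returned for display.
#'
#' @param x unit-scale matrix.
#' @param models list of `gan_model` bundles (odd length matching the
#'   configured ensemble size).
#' @param cfg an [anomaly_config()].
#' @param mode "restore" or "encoder" reconstruction.
#' @param restore_cfg a [restoration_config()] for restore mode.
#' @return list with `mask`, `per_model_masks`, `residuals`,
#'   `reconstructions`, `mean_reconstruction`.
#' @export
detect <- function(x, models, cfg = anomaly_config(),
                   mode = c("restore", "encoder"),
                   restore_cfg = restoration_config()) {
  mode <- match.arg(mode)
  stopifnot(is.list(models), length(models) == cfg$ensemble_size)
  x <- unclass(x)
  N <- nrow(x)
  for (m in models)
    if (m$generator$meta$resolution != N)
      stop("model resolution does not match the input image")
  radius <- if (is.null(cfg$closing_radius)) default_closing_radius(N)
            else cfg$closing_radius
  recons <- lapply(models, function(m)
    reconstruct_image(x, m, mode = mode, restore_cfg = restore_cfg))
  residuals <- lapply(recons, function(xh)
    residual_map(x, xh, cfg$residual_kind, "byte"))
  per_model <- lapply(residuals, function(r)
    close_mask(threshold_mask(r, cfg$threshold), radius))
  list(mask = majority_vote(per_model),
       per_model_masks = per_model,
       residuals = residuals,
       reconstructions = recons,
       mean_reconstruction = Reduce(`+`, recons) / length(recons))
}
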