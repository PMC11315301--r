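# Training-time image augmentation: random mirroring, contrast changes and
# translation for the GAN; random rectangle erasing for the encoder.

#' Augmentation settings
#'
#' @param mirror_prob probability of a horizontal flip.
#' @param contrast_range range of the multiplicative contrast factor applied
#'   about the image mean.
#' @param translate_frac maximum translation in either axis, as a fraction of
#'   the image width (shifted-in pixels are zero).
#' @export
augment_config <- function(mirror_prob = 0.5, contrast_range = c(0.8, 1.25),
                           translate_frac = 0.05) {
  stopifnot(mirror_prob >= 0, mirror_prob <= 1,
            length(contrast_range) == 2, contrast_range[1] <= contrast_range[2],
            contrast_range[1] > 0, translate_frac >= 0)
  structure(list(mirror_prob = mirror_prob, contrast_range = contrast_range,
                 translate_frac = translate_frac), class = "augment_config")
}

shift_image <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- max(1, 1 - dy):min(H, H - dy)
  src_c <- max(1, 1 - dx):min(W, W - dx)
  if (length(src_r) > 0 && length(src_c) > 0)
    out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}

#' Randomly augment a unit-scale slice image
#'
#' Applies, in order: horizontal mirroring, a contrast change about the image
#' mean, and an integer translation with zero padding.  With all probabilities
#' and magnitudes zero the image is returned unchanged.  Randomness is drawn
#' from the current RNG stream, so a seeded caller gets deterministic output.
#'
#' @param img unit-scale matrix.
#' @param settings an [augment_config()].
#' @return augmented unit-scale matrix (clamped to \[0,1\]).
#' @export
augment <- function(img, settings = augment_config()) {
  stopifnot(is.matrix(img))
  if (settings$mirror_prob > 0 && stats::runif(1) < settings$mirror_prob)
    img <- img[, ncol(img):1, drop = FALSE]
  cr <- settings$contrast_range
  if (cr[1] != 1 || cr[2] != 1) {
    s <- stats::runif(1, cr[1], cr[2])
    m <- mean(img)
    img <- m + s * (img - m)
  }
  if (settings$translate_frac > 0) {
    mx <- round(settings$translate_frac * ncol(img))
    d <- sample.int(2L * mx + 1L, 2L, replace = TRUE) - mx - 1L
    img <- shift_image(img, d[1], d[2])
  }
  pmin(pmax(img, 0), 1)
}

#' Randomly erase a rectangle from an image
#'
#' With probability `erase_prob` one axis-aligned rectangle (side lengths
#' uniform within `erase_frac` of the image width) is set to the background
#' value; otherwise the image is returned unchanged.  Used during encoder
#' training so the encoder cannot learn the identity mapping.
#'
#' @param img unit-scale matrix.
#' @param erase_prob probability of erasing (default the training value 0.25).
#' @param erase_frac range of rectangle side lengths as fractions of width.
#' @param background value written into the rectangle.
#' @return image with at most one erased rectangle.
#' @export
random_erase <- function(img, erase_prob = 0.25, erase_frac = c(0.10, 0.35),
                         background = 0) {
  stopifnot(is.matrix(img), erase_prob >= 0, erase_prob <= 1)
  if (erase_prob == 0 || stats::runif(1) >= erase_prob) return(img)
  H <- nrow(img); W <- ncol(img)
  eh <- max(1L, round(stats::runif(1, erase_frac[1], erase_frac[2]) * W))
  ew <- max(1L, round(stats::runif(1, erase_frac[1], erase_frac[2]) * W))
  eh <- min(eh, H); ew <- min(ew, W)
  r0 <- sample.int(H - eh + 1L, 1L)
  c0 <- sample.int(W - ew + 1L, 1L)
  img[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L)] <- background
  img
}
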