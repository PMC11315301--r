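# Synthetic head-phantom slices: a bright elliptical skull annulus, mid-gray
# brain tissue with smooth low-amplitude texture (the low-contrast regime the
# method must cope with), darker paired ventricles, and insertable lesions
# with exact ground-truth masks.  Per-image geometry is drawn from a
# counter-based substream, so sample i does not depend on how many samples
# are requested.

#' Phantom population specification
#'
#' All geometric quantities are fractions of the image size.  Intensity
#' conventions: background 0, brain tissue ~0.35, ventricles ~0.15,
#' skull ~0.95, everything clamped to \[0,1\].
#'
#' @param resolution image size (power of two >= 32).
#' @param skull_radius_range range of the outer skull semi-axis.
#' @param skull_thickness_range range of the skull annulus thickness.
#' @param ventricle_count number of ventricle ellipses (0 disables).
#' @param ventricle_size_range range of ventricle diameters.
#' @param tissue_contrast amplitude of the smooth intra-tissue texture.
#' @param noise_sd additive Gaussian noise level.
#' @param seed base seed of the per-image substreams.
#' @export
phantom_spec <- function(resolution = 512,
                         skull_radius_range = c(0.34, 0.40),
                         skull_thickness_range = c(0.045, 0.065),
                         ventricle_count = 2,
                         ventricle_size_range = c(0.05, 0.10),
                         tissue_contrast = 0.04,
                         noise_sd = 0.01,
                         seed = 1) {
  .check_pow2(resolution, lo = 32)
  chk <- function(r) length(r) == 2 && all(r > 0) && all(r < 1) && r[1] <= r[2]
  stopifnot(chk(skull_radius_range), chk(skull_thickness_range),
            chk(ventricle_size_range), ventricle_count >= 0,
            tissue_contrast >= 0, noise_sd >= 0)
  structure(list(resolution = resolution,
                 skull_radius_range = skull_radius_range,
                 skull_thickness_range = skull_thickness_range,
                 ventricle_count = as.integer(ventricle_count),
                 ventricle_size_range = ventricle_size_range,
                 tissue_contrast = tissue_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

.substream_seed <- function(seed, i, stream = 0L) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(i) * 9973 +
                as.numeric(stream) * 7129) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  expr
}

.ellipse_mask <- function(N, cx, cy, a, b, theta = 0) {
  xv <- (seq_len(N) - 0.5) / N
  X <- matrix(xv, N, N, byrow = TRUE)  # column coordinate
  Y <- matrix(xv, N, N)                # row coordinate
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma))
}

.render_phantom <- function(spec) {
  N <- spec$resolution
  cx <- stats::runif(1, 0.49, 0.51)
  cy <- stats::runif(1, 0.49, 0.51)
  a_out <- stats::runif(1, spec$skull_radius_range[1], spec$skull_radius_range[2])
  b_out <- min(a_out * stats::runif(1, 1.08, 1.22), 0.47)
  th <- stats::runif(1, spec$skull_thickness_range[1], spec$skull_thickness_range[2])
  theta <- stats::runif(1, -0.08, 0.08)
  outer <- .ellipse_mask(N, cx, cy, a_out, b_out, theta)
  brain <- .ellipse_mask(N, cx, cy, a_out - th, b_out - th, theta)
  img <- matrix(0, N, N)
  img[outer & !brain] <- 0.95
  img[brain] <- 0.35
  if (spec$tissue_contrast > 0) {
    tx <- .gauss_blur(matrix(stats::rnorm(N * N), N, N), 0.03 * N)
    s <- stats::sd(tx[brain])
    if (is.finite(s) && s > 1e-12) {
      tx <- (tx - mean(tx[brain])) / s * spec$tissue_contrast
      img[brain] <- 0.35 + tx[brain]
    }
  }
  if (spec$ventricle_count > 0) {
    for (j in seq_len(spec$ventricle_count)) {
      side <- if (j %% 2 == 1) -1 else 1
      dxv <- side * stats::runif(1, 0.045, 0.075)
      dyv <- stats::runif(1, -0.05, 0.0)
      av <- stats::runif(1, spec$ventricle_size_range[1],
                         spec$ventricle_size_range[2]) / 2
      bv <- av * stats::runif(1, 1.6, 2.2)
      tv <- side * stats::runif(1, 0.15, 0.35)
      vm <- .ellipse_mask(N, cx + dxv, cy + dyv, av, bv, tv) & brain
      img[vm] <- 0.15
    }
  }
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(N * N, sd = spec$noise_sd), N, N)
  img <- pmin(pmax(img, 0), 1)
  attr(img, "brain_mask") <- brain
  attr(img, "scale") <- "unit"
  img
}

#' Generate a phantom dataset
#'
#' Deterministic for a fixed `(spec, n)`: identical calls produce
#' bit-identical datasets, and the i-th sample is the same regardless of `n`.
#' Each phantom is treated as its own patient.
#'
#' @param spec a [phantom_spec()].
#' @param n number of images (>= 1).
#' @param split split tag for the resulting dataset.
#' @return a [slice_dataset()] of unit-scale square images; each image
#'   carries a `brain_mask` attribute marking the intracranial region.
#' @export
generate_phantom <- function(spec, n, split = "train") {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  images <- lapply(seq_len(n), function(i)
    .with_seed(.substream_seed(spec$seed, i), .render_phantom(spec)))
  ids <- sprintf("P%d-%05d", spec$seed, seq_len(n))
  slice_dataset(images, ids, split)
}

#' Lesion specification
#'
#' `bright_blob` is a smooth positive intensity offset (acute-hemorrhage
#' analogue, hence `intensity_delta > 0`); `textured_mass` adds
#' high-frequency texture on top of the offset (heterogeneous-tumor
#' analogue).
#'
#' @param kind "bright_blob" or "textured_mass".
#' @param center lesion center, pixel coordinates c(row, col).
#' @param radius lesion radius in pixels (0 means no lesion).
#' @param intensity_delta signed unit-scale offset.
#' @param seed seed of the texture substream.
#' @param texture_amp texture amplitude for `textured_mass`.
#' @export
anomaly_spec <- function(kind = c("bright_blob", "textured_mass"), center,
                         radius, intensity_delta, seed = 1,
                         texture_amp = 0.08) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2, radius >= 0)
  if (kind == "bright_blob" && intensity_delta <= 0)
    stop("bright_blob lesions are brighter than tissue: intensity_delta must be > 0")
  structure(list(kind = kind, center = as.numeric(center), radius = radius,
                 intensity_delta = intensity_delta, seed = as.integer(seed),
                 texture_amp = texture_amp), class = "anomaly_spec")
}

.disk_mask <- function(dim2, center, radius) {
  if (radius <= 0) return(matrix(FALSE, dim2[1], dim2[2]))
  R <- matrix(seq_len(dim2[1]), dim2[1], dim2[2])
  C <- matrix(seq_len(dim2[2]), dim2[1], dim2[2], byrow = TRUE)
  (R - center[1])^2 + (C - center[2])^2 <= radius^2
}

#' Insert a lesion into a phantom slice
#'
#' The returned mask is exactly the lesion footprint (a discrete disk);
#' outside the mask the image is unchanged and the result is clamped to
#' \[0,1\].  The lesion must lie inside the image and, when a brain mask is
#' available (argument or `brain_mask` attribute), inside the brain region.
#'
#' @param img unit-scale matrix.
#' @param aspec an [anomaly_spec()].
#' @param brain_mask optional logical matrix overriding the image attribute.
#' @return list with `image` (lesioned, attributes preserved) and `mask`.
#' @export
insert_anomaly <- function(img, aspec, brain_mask = NULL) {
  stopifnot(is.matrix(img), inherits(aspec, "anomaly_spec"))
  d <- dim(img)
  ctr <- aspec$center; r <- aspec$radius
  if (ctr[1] - r < 1 || ctr[1] + r > d[1] || ctr[2] - r < 1 || ctr[2] + r > d[2])
    stop("lesion footprint extends outside the image bounds")
  mask <- .disk_mask(d, ctr, r)
  bm <- if (!is.null(brain_mask)) brain_mask else attr(img, "brain_mask")
  if (!is.null(bm) && any(mask & !bm))
    stop("lesion placement error: footprint leaves the brain region")
  out <- unclass(img)
  if (any(mask)) {
    delta <- aspec$intensity_delta
    if (aspec$kind == "textured_mass") {
      tex <- .with_seed(.substream_seed(aspec$seed, 1L, stream = 11L),
                        matrix(stats::rnorm(prod(d), sd = aspec$texture_amp),
                               d[1], d[2]))
      out[mask] <- out[mask] + delta + tex[mask]
    } else {
      out[mask] <- out[mask] + delta
    }
    out <- pmin(pmax(out, 0), 1)
  }
  attributes(out) <- attributes(img)
  list(image = out, mask = mask)
}

#' Generate an abnormal phantom dataset with ground-truth masks
#'
#' Each phantom receives one lesion with radius and intensity offset drawn
#' from the given ranges, placed uniformly among the positions whose full
#' footprint fits inside the brain region.
#'
#' @param spec a [phantom_spec()] (use a different `seed` than the training
#'   population so patients never overlap splits).
#' @param n number of images.
#' @param kind lesion kind, see [anomaly_spec()].
#' @param radius_frac range of lesion radii as fractions of image width.
#' @param delta range of intensity offsets.
#' @param split split tag ("validation" or "test").
#' @return a [slice_dataset()] with reference masks.
#' @export
phantom_with_lesions <- function(spec, n, kind = "bright_blob",
                                 radius_frac = c(0.08, 0.12),
                                 delta = c(0.25, 0.40),
                                 split = "test") {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  N <- spec$resolution
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- .with_seed(.substream_seed(spec$seed, i), .render_phantom(spec))
    les <- .with_seed(.substream_seed(spec$seed, i, stream = 5L), {
      r_px <- max(2L, round(stats::runif(1, radius_frac[1], radius_frac[2]) * N))
      dl <- stats::runif(1, delta[1], delta[2])
      brain <- attr(img, "brain_mask")
      repeat {
        allowed <- EBImage::erode(brain * 1, EBImage::makeBrush(2L * r_px + 1L, "disc")) > 0.5
        if (any(allowed) || r_px <= 2L) break
        r_px <- r_px - 1L
      }
      pos <- which(allowed)
      ctr <- arrayInd(pos[sample.int(length(pos), 1L)], dim(img))
      insert_anomaly(img, anomaly_spec(kind, center = as.numeric(ctr),
                                       radius = r_px, intensity_delta = dl,
                                       seed = .substream_seed(spec$seed, i, 7L)))
    })
    images[[i]] <- les$image
    masks[[i]] <- les$mask
  }
  ids <- sprintf("P%d-%05d", spec$seed, seq_len(n))
  slice_dataset(images, ids, split, masks)
}
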