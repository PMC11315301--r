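# Slice-image IO and dataset assembly.
#
# Images are unit-scale grayscale matrices [row, col].  PNG (8/16-bit
# grayscale), NIfTI (via RNifti) and single-frame uncompressed DICOM are
# supported.  Hounsfield-valued inputs (DICOM/NIfTI) can be windowed with a
# standard (center, width) display window; the default brain window is
# 40/80 HU.

#' Construct an image grid
#'
#' A validated grayscale intensity raster.  Unit-scale grids must lie in
#' \[0,1\]; no undefined values are allowed.
#'
#' @param pixels numeric matrix.
#' @param scale one of "unit", "byte", "hounsfield".
#' @return the matrix with class `image_grid` and a `scale` attribute.
#' @export
image_grid <- function(pixels, scale = c("unit", "byte", "hounsfield")) {
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("empty image")
  if (any(!is.finite(pixels))) stop("image contains undefined values")
  if (scale == "unit" && (min(pixels) < 0 || max(pixels) > 1))
    stop("unit-scale image has values outside [0,1]")
  if (scale == "byte" && (min(pixels) < 0 || max(pixels) > 255))
    stop("byte-scale image has values outside [0,255]")
  structure(pixels, scale = scale, class = c("image_grid", class(pixels)))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %dx%d, %s scale, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "scale"), min(x), max(x)))
  invisible(x)
}

#' Min-max normalize an image to \[0,1\]
#'
#' Affine rescaling of the intensity range; a constant image maps to all
#' zeros (backgrounds are dark in CT, and this avoids division by zero).
#' Idempotent on its own output.
#'
#' @param img numeric matrix.
#' @return unit-scale matrix (attributes other than `scale` preserved).
#' @export
normalize_unit <- function(img) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  out <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  attributes(out) <- attributes(img)
  attr(out, "scale") <- "unit"
  out
}

.apply_window <- function(hu, window) {
  stopifnot(length(window) == 2, window[2] > 0)
  lo <- window[1] - window[2] / 2
  pmin(pmax((hu - lo) / window[2], 0), 1)
}

#' Load a 2D slice image
#'
#' Reads PNG (8/16-bit grayscale), NIfTI, or single-frame uncompressed
#' little-endian DICOM and returns a unit-scale [image_grid()].  For
#' Hounsfield-valued formats (DICOM, NIfTI) a display `window = c(center,
#' width)` maps `center - width/2 -> 0` and `center + width/2 -> 1` with
#' clamping; without a window, intensities are min-max normalized.  Color
#' PNG input is rejected rather than converted.
#'
#' @param path file path.
#' @param format "auto" (by extension), "png", "nifti", or "dicom".
#' @param window optional (center, width) in HU; only valid for DICOM/NIfTI.
#' @param slice slice index for 3D NIfTI volumes.
#' @return unit-scale [image_grid()].
#' @export
load_slice <- function(path, format = c("auto", "png", "nifti", "dicom"),
                       window = NULL, slice = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom"
      else stop("cannot infer format from extension of ", path)
  }
  if (format == "png") {
    if (!is.null(window)) stop("windowing applies to HU-valued formats only")
    px <- try(png::readPNG(path), silent = TRUE)
    if (inherits(px, "try-error")) stop("unreadable PNG file: ", path)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3] == 2L) px <- px[, , 1L]  # gray + alpha: drop alpha
      else stop("color PNG input is not supported; provide grayscale")
    }
    return(image_grid(px, "unit"))
  }
  hu <- if (format == "nifti") {
    v <- try(as.array(RNifti::readNifti(path)), silent = TRUE)
    if (inherits(v, "try-error")) stop("unreadable NIfTI file: ", path)
    d <- dim(v)
    if (length(d) == 3L && d[3] == 1L) { dim(v) <- d[1:2]; v }
    else if (length(d) == 3L) {
      if (is.null(slice)) stop("3D NIfTI volume: a slice index is required")
      v[, , slice]
    } else if (length(d) == 2L) v
    else stop("non-2D NIfTI payload with ", length(d), " dimensions")
  } else {
    dc <- read_dicom_slice(path)
    dc$slope * dc$pixels + dc$intercept
  }
  if (any(!is.finite(hu))) stop("image contains undefined values")
  out <- if (!is.null(window)) .apply_window(hu, window) else normalize_unit(hu)
  image_grid(unclass(out), "unit")
}

#' Save a unit-scale slice image
#'
#' PNG output is 8-bit grayscale; NIfTI stores the floating-point values.
#'
#' @param img unit-scale matrix.
#' @param path destination; format inferred from extension (.png / .nii).
#' @export
save_slice <- function(img, path) {
  img <- pmin(pmax(unclass(img), 0), 1)
  attributes(img) <- list(dim = dim(img))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(img), path)
  } else stop("unsupported output format for ", path)
  invisible(path)
}

#' Construct a slice dataset
#'
#' An ordered collection of equally-keyed images with per-image patient
#' identifiers, a split tag, and (for validation/test splits) optional
#' reference lesion masks.  The training split is normal-only and must not
#' carry masks.
#'
#' @param images list of unit-scale matrices.
#' @param patient_ids character vector parallel to `images`.
#' @param split "train", "validation", or "test".
#' @param masks optional list of logical matrices parallel to `images`.
#' @export
slice_dataset <- function(images, patient_ids,
                          split = c("train", "validation", "test"),
                          masks = NULL) {
  split <- match.arg(split)
  stopifnot(is.list(images), length(images) >= 1,
            length(patient_ids) == length(images))
  if (split == "train" && !is.null(masks))
    stop("the training split is normal-only and must not carry lesion masks")
  for (im in images) {
    if (!is.matrix(im)) stop("images must be matrices")
    if (any(!is.finite(im))) stop("image contains undefined values")
  }
  if (!is.null(masks)) {
    stopifnot(length(masks) == length(images))
    for (i in seq_along(masks)) {
      if (!identical(dim(masks[[i]]), dim(images[[i]])))
        stop("mask ", i, " does not match its image dimensions")
      if (!is.logical(masks[[i]])) stop("masks must be logical matrices")
    }
  }
  structure(list(images = images, patient_ids = as.character(patient_ids),
                 split = split, masks = masks), class = "slice_dataset")
}

#' @export
print.slice_dataset <- function(x, ...) {
  cat(sprintf("<slice_dataset '%s': %d images, %d patients%s>\n", x$split,
              length(x$images), length(unique(x$patient_ids)),
              if (is.null(x$masks)) "" else ", with masks"))
  invisible(x)
}

#' Assemble one or more slice datasets with patient-level split integrity
#'
#' With a scalar `split`, returns a single [slice_dataset()].  With a
#' per-image split vector, returns a named list of datasets and raises an
#' error if any patient appears in more than one split (images from one
#' patient are only ever used for one of training and testing).
#'
#' @param images list of unit-scale matrices.
#' @param patient_ids character vector parallel to `images`.
#' @param split scalar split tag, or one tag per image.
#' @param masks optional list parallel to `images` (entries may be NULL).
#' @export
assemble_dataset <- function(images, patient_ids, split, masks = NULL) {
  if (length(split) == 1L)
    return(slice_dataset(images, patient_ids, split, masks))
  stopifnot(length(split) == length(images))
  per_patient <- tapply(split, patient_ids, function(s) length(unique(s)))
  bad <- names(per_patient)[per_patient > 1]
  if (length(bad) > 0)
    stop("patient(s) assigned to more than one split: ",
         paste(bad, collapse = ", "))
  out <- list()
  for (s in intersect(c("train", "validation", "test"), unique(split))) {
    idx <- which(split == s)
    mk <- if (is.null(masks)) NULL else masks[idx]
    if (!is.null(mk) && all(vapply(mk, is.null, logical(1)))) mk <- NULL
    out[[s]] <- slice_dataset(images[idx], patient_ids[idx], s, mk)
  }
  out
}

#' Read / write plain-text dataset manifests
#'
#' Tab-separated tables with columns `path`, `patient_id`, `split` and
#' optional `mask_path`.
#'
#' @param path manifest file path.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "patient_id", "split")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param manifest data frame as returned by [read_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Load datasets listed in a manifest
#'
#' @param path manifest path; relative image paths are resolved against the
#'   manifest directory.
#' @param window optional HU display window forwarded to [load_slice()].
#' @return named list of [slice_dataset()]s, one per split present.
#' @export
load_datasets <- function(path, window = NULL) {
  df <- read_manifest(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.path(base, p) == p | grepl("^/", p),
                                p, file.path(base, p))
  images <- lapply(resolve(df$path), function(p) {
    fmt <- if (grepl("\\.png$", p, ignore.case = TRUE)) NULL else window
    unclass(load_slice(p, window = fmt))
  })
  masks <- NULL
  if ("mask_path" %in% names(df)) {
    masks <- lapply(seq_len(nrow(df)), function(i) {
      mp <- df$mask_path[i]
      if (is.na(mp) || mp == "") NULL
      else unclass(load_slice(resolve(mp))) > 0.5
    })
  }
  assemble_dataset(images, df$patient_id, df$split, masks)
}
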