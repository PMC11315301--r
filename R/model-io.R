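# Serialization of trained model bundles.

#' Save / load a trained model bundle
#'
#' Bundles are stored as RDS containers carrying the network parameters
#' together with their resolution, latent-dimension, step and seed metadata.
#'
#' @param model a `gan_model` (optionally with `$encoder`) or
#'   `encoder_model`.
#' @param path destination file.
#' @export
save_model_bundle <- function(model, path) {
  stopifnot(inherits(model, c("gan_model", "encoder_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("gan_model", "encoder_model")))
    stop("file does not contain a model bundle: ", path)
  m
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("<gan_model: %dx%d, latent %d, %d steps%s>\n",
              x$generator$meta$resolution, x$generator$meta$resolution,
              x$generator$meta$latent_dim, nrow(x$log),
              if (!is.null(x$encoder)) ", with encoder" else ""))
  invisible(x)
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model: %dx%d -> latent %d, %d steps>\n",
              x$encoder$meta$resolution, x$encoder$meta$resolution,
              x$encoder$meta$latent_dim, nrow(x$log)))
  invisible(x)
}
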