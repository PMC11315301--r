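# Adversarial losses: hinge form for the discriminator, non-saturating mean
# logit for the generator, plus the discriminator's auxiliary self-supervised
# reconstruction loss.

#' Generator adversarial loss
#'
#' The generator minimizes the negative mean discriminator logit of generated
#' samples, \eqn{L_G = -\mathrm{mean}(D(G(z)))}.
#'
#' @param fake_logits numeric vector of discriminator logits on generated
#'   images.
#' @return scalar loss.
#' @export
generator_loss <- function(fake_logits) {
  stopifnot(length(fake_logits) > 0, is.numeric(fake_logits))
  -mean(fake_logits)
}

#' Discriminator hinge loss
#'
#' \eqn{L_D = \mathrm{mean}(\max(0, 1 - D(x))) +
#'       \mathrm{mean}(\max(0, 1 + D(G(z)))) + L_{rec}},
#' where the reconstruction term comes from the discriminator's auxiliary
#' decoder on real inputs (see [reconstruction_loss()]).
#'
#' @param real_logits,fake_logits numeric logit vectors.
#' @param rec_loss non-negative auxiliary reconstruction loss.
#' @return scalar loss (always >= 0).
#' @export
discriminator_loss <- function(real_logits, fake_logits, rec_loss = 0) {
  stopifnot(length(real_logits) > 0, length(fake_logits) > 0, rec_loss >= 0)
  mean(pmax(0, 1 - real_logits)) + mean(pmax(0, 1 + fake_logits)) + rec_loss
}

#' Auxiliary discriminator reconstruction loss
#'
#' Mean absolute error between the discriminator decoder's low-resolution
#' output and the correspondingly downsampled real image.  Zero exactly when
#' the decoded image equals the downsampled input.
#'
#' @param real_image real input downsampled to the decoder resolution
#'   (matrix or [H,W,1,B] array).
#' @param decoded decoder output of the same shape.
#' @return scalar mean absolute error.
#' @export
reconstruction_loss <- function(real_image, decoded) {
  real_image <- as_batch_array(real_image)
  decoded <- as_batch_array(decoded)
  if (!identical(dim(real_image), dim(decoded)))
    stop("shape mismatch: decoded is ", paste(dim(decoded), collapse = "x"),
         ", downsampled real is ", paste(dim(real_image), collapse = "x"))
  mean(abs(decoded - real_image))
}

# k-fold 2x average-pooling (used to build the 8x-downsampled decoder target)
downsample_pow2 <- function(x, times) {
  x <- as_batch_array(x)
  for (i in seq_len(times)) x <- cpp_avgpool2(x)
  x
}
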