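Package: pseudohealthy
Title: GAN-Based Pseudo-Healthy Reconstruction and Anomaly Detection for Brain CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Unsupervised anomaly detection for axial brain computed-tomography
    slices. A generative adversarial network with hinge losses, spectral
    normalization and a self-supervised discriminator decoder is trained on
    normal slices only; unseen images are inverted into the latent space either
    by a trained encoder or by per-image iterative latent restoration, and
    anomalies are segmented from reconstruction residuals by thresholding,
    morphological closing and a majority-vote model ensemble. Includes a
    synthetic head-phantom generator with exact ground-truth lesion masks, so
    the full pipeline can be trained and evaluated end-to-end without external
    data, plus Dice / pixel-pooled ROC / reconstruction-error evaluation tools.
    All network machinery is implemented in the package with explicit
    backpropagation and compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    digest,
    png,
    RNifti,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
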