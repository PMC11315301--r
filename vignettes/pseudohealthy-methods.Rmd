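---
title: "Pseudo-healthy reconstruction and residual anomaly detection for brain CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-healthy reconstruction and residual anomaly detection for brain CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`pseudohealthy` detects anomalies in axial brain-CT slices without ever
seeing an annotated lesion.  The idea has three stages:

1. **Learn normal anatomy.**  A generative adversarial network is trained on
   normal slices only.  The generator $G$ maps latent codes
   $z \sim U[-1,1]^L$ to images; the discriminator $D$ is trained with the
   hinge objective
   $$L_D = \mathbb{E}_x[\max(0, 1 - D(x))] +
     \mathbb{E}_z[\max(0, 1 + D(G(z)))] + L_{rec},$$
   and the generator with the non-saturating form
   $L_G = -\mathbb{E}_z[D(G(z))]$.  $L_{rec}$ is a self-supervision term: an
   auxiliary decoder head on the discriminator must reproduce an
   8×-downsampled version of every real input from the 4×4 feature map, as
   the mean absolute error between the decoded image and the downsampled
   input.  This forces the discriminator to retain image content rather than
   collapse to a binary detector, and is what makes the architecture work on
   small training sets.  All discriminator weights carry spectral
   normalization (one power iteration per forward pass); the generator uses
   batch-norm + GLU upsampling blocks, learned per-block noise injection and
   one skip-layer excitation connection, following the lightweight-GAN
   design family.

2. **Invert unseen images.**  A test slice $x$ is mapped to a latent code
   so that $G(z) \approx x$.  Two interchangeable routes are provided:
   * a trained **encoder** $E$ minimizing
     $w_1\,\ell_{percept}(x, G(E(x))) + w_2\,\ell_{MSE}(x, G(E(x)))$
     with $w_1 = 1$, $w_2 = 10$, over inputs with randomly erased
     rectangles (probability 0.25) so the identity mapping is not learnable;
   * per-image **latent restoration**: the same objective minimized over
     $z$ directly with Adam, starting from $z = 0$ and clipping every
     iterate component-wise to $[-1,1]$ (8000 steps at full scale).
   Because only normal anatomy is representable by $G$, lesions cannot be
   reproduced: the reconstruction is a *pseudo-healthy* version of the input.

3. **Segment the residual.**  The difference map $\rho(x - \hat x)$ — with
   $\rho = |\cdot|$ for arbitrary lesions or $\rho = \max(\cdot, 0)$ for
   hyperdense (hemorrhage-like) ones — is expressed in byte-scale intensity
   units (0–255), thresholded at an operating point chosen on a validation
   split by maximizing median Dice, refined by morphological closing, and
   combined across three independently trained GANs by per-pixel majority
   vote.  A 26-connectivity component filter across consecutive slices can
   remove small false positives in volumetric use.

## The perceptual distance

The reconstruction objective uses an LPIPS-style distance: features from a
fixed convolutional stack are unit-normalized along the channel axis at
every position and compared by mean squared difference, summed over three
tapped layers.  The package's default backend is a **fixed-seed stack of
random convolution filters** (5×5 and 3×3, strides 2).  Random-feature
perceptual metrics are a known, dependency-free member of this family; they
are weaker than a metric built on pretrained classification features, but
keep the package fully self-contained and offline.  The backend registry
(`register_percept_backend()`) accepts any alternative feature extractor
without changing any caller; the backward pass is part of the backend
contract because encoder training and restoration differentiate through it.

## What the phantom generator emulates — and what it does not

The built-in head phantom provides the entire data supply at desk scale: a
bright elliptical skull annulus (~0.95), mid-gray brain tissue (~0.35) with
smooth low-amplitude texture (band-limited Gaussian noise, amplitude 0.04)
emulating the low soft-tissue contrast of CT, darker paired ventricles
(~0.15), additive noise (sd 0.01), and per-image variation in skull size
(outer semi-axis 0.34–0.40 of the image), elongation, thickness
(0.045–0.065), rotation and ventricle geometry.  Each image is drawn from a
counter-based substream, so sample *i* is independent of the number of
samples requested and datasets are bit-reproducible.

Lesions are inserted with exact ground-truth masks: `bright_blob` adds a
positive offset on a disk (acute-hemorrhage analogue; the offset range
0.25–0.40 against 0.35 tissue mirrors the hyperdensity of fresh blood),
`textured_mass` additionally superimposes high-frequency texture
(heterogeneous-tumor analogue).

The phantom deliberately omits: gyral/sulcal anatomy, gray–white matter
differentiation, beam hardening and streak artifacts, partial-volume
effects, and anatomical left–right asymmetries.  Passing the end-to-end
tests therefore demonstrates that the *machinery* — adversarial training,
latent inversion, residual thresholding, ensembling, evaluation — behaves
correctly and recovers lesions under CT-like contrast ordering.  It does
not demonstrate clinical performance on real scans, which depends on the
generator capturing far richer anatomy.

## Study sizes and numerical choices

Full-scale defaults: 512×512 images, latent
dimension 512, batch 8, learning rate 2e-4 with Adam, 100,000 GAN steps,
20,000 encoder steps, 8000 restoration steps.  The package's desk-scale
study (`demo_run_config()`), used by the test suite and the acceptance
script, is chosen once as: 32×32 phantoms, latent dimension 64, base width
4 (cap 64), 64 training phantoms, a 3-model ensemble at 2000 steps per
member, restoration with 200 steps at learning rate 0.05, 8 validation and
20 test images.  These sizes keep a complete experiment within tens of
minutes on one CPU while preserving every structural element (depth rules,
ensembling, operating-point selection).

Other numerical decisions:

* **Architecture depth rules.**  Generator upsampling blocks:
  $\log_2 N - 2$ (7 at 512 — one fewer than a full 4→1024 pyramid);
  encoder down-sampling blocks: $\log_2 N - 1$ (8 at 512); discriminator
  strided convolutions: $\log_2 N - 2$ down to a 4×4 feature map whose
  auxiliary decoder reconstructs the 8×-downsampled input.
* **Adam moments** (0.5, 0.999) for both adversaries — the conventional
  GAN setting; restoration uses the default (0.9, 0.999).
* **Spectral normalization** uses one power iteration per training forward
  pass with the standard gradient that treats the singular vectors as
  constants; at convergence of the power iteration this is the exact
  gradient (envelope argument), which the test suite verifies numerically.
* **Batch norm** uses momentum 0.9 running statistics.  After GAN training
  the generator always runs in inference mode (frozen statistics), so
  encoder training, restoration and detection see a deterministic,
  batch-independent generator.
* **Residual scale.**  Residuals are multiplied by 255 before
  thresholding, so operating points are reported in display-intensity
  units; comparison is strict (`> t`).
* **Closing element**: disk of radius 2 at 512 resolution, scaled
  proportionally (`round(2 N / 512)`), hence a no-op at 32×32.  Closing
  pads with background for the dilation and with foreground for the
  erosion, which keeps it extensive and idempotent at image borders.
* **Degenerate cases.**  Min-max normalization maps constant images to
  zero; Dice of two empty masks is defined as 1 and flagged; a lesion of
  radius 0 is an empty mask; an even ensemble is rejected (no tie rule).
* **Randomness.**  Every training function seeds the RNG from its config;
  ensemble members use seeds `seed + 0, 1, 2`; phantom images use
  counter-based substreams.  Two runs of `run_experiment()` with one seed
  produce identical reports.

## Design choices where the design was genuinely open

* The random-erase augmentation is applied to the encoder *input* only;
  the loss target is the un-erased image.  The alternative (erasing the
  target too) would train the encoder to reproduce the erasure, which
  contradicts the purpose of the augmentation.
* The encoder output is squashed by `tanh`, matching the support of the
  uniform latent prior; without it, codes could leave the region on which
  the generator was ever trained.
* ROC curves pool pixels across images (a per-image average is the other
  convention); the pooled choice is recorded in the evaluation output.
* Per-lesion Dice for the detection rate scores each connected reference
  component against the prediction restricted to a dilated neighbourhood
  of that component, so unrelated false positives elsewhere in the image
  do not dilute a lesion's score.
* Operating-point ties resolve to the smallest threshold (more sensitive
  at equal validation Dice).
* For DICOM input the default display window is the standard brain window
  (center 40 HU, width 80 HU); per-slice min-max normalization is the
  fallback when no window is given.

## Known limitations

* The desk-scale generator is far too small to model real anatomy; results
  at 32×32 are a mechanism check, not a clinical benchmark.
* The random-feature perceptual backend is weaker than pretrained-feature
  metrics; swap in a stronger backend via the registry where downloads are
  possible.
* Training is single-CPU and synchronous; at 512×512 the full-scale
  conditions are configurable but not practical without substantial
  compute.
* The DICOM reader covers uncompressed little-endian single-frame files
  only; compressed transfer syntaxes are rejected with a clear error.
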