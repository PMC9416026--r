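---
title: "Generating and validating hyperspectral skin-lesion cubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and validating hyperspectral skin-lesion cubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hsigan` synthesizes labeled hyperspectral skin-lesion image cubes with
a conditional deep convolutional GAN and quantifies how faithful the
synthetic data is.  This vignette explains the models, the assumptions
behind them, the tunable parameters, and the design decisions taken
where the method left room for choice.  It is the place to read before
trusting any number the package produces.

## 1. Data model and preprocessing

A hyperspectral cube is a `height x width x bands` reflectance array
with a strictly increasing wavelength axis, an optional binary lesion
mask (1 = lesion) and an optional class label (benign / malignant).
The default axis models a visible/near-infrared snapshot camera: 125
bands on a linear grid from 450 to 950 nm.  The nominal 8 nm spectral
resolution quoted for such cameras is inconsistent with 125 bands over
a 500 nm range; the package adopts the linear 125-sample grid
(spacing about 4 nm) and treats the exact band centers as unknown.

Raw sensor counts become reflectance through the standard flat-field
rule `(raw - dark) / (white - dark)`, where `white` images a
reflectance standard and `dark` is a closed-shutter frame.  The result
is clipped to `[0, 2]`: specular glints can exceed the standard's
reflectance, and an unbounded value would break the affine mapping to
the generator's tanh range.  A zero `white - dark` denominator is a
degenerate acquisition and raises an error naming the voxel rather than
propagating infinities.  The first five and last four bands carry high
sensor noise at the edges of the sensitivity range and are removed by
`trim_bands()`, leaving 116 bands spanning roughly 470–934 nm; trimming
and calibration are element-wise and commute, which the test suite
checks.

Class labels are *smoothed* before they reach any network: malignant
maps to a uniform draw in `[0.7, 1]`, benign to `[0, 0.3]`.  Hard 0/1
targets make the discriminator overconfident on tiny datasets; the
interval encoding also gives the conditional generator a continuous
input.  Smoothed values are re-drawn every epoch so the discriminator
cannot memorize fixed targets.

Datasets are stored either as one ENVI text header + band-sequential
binary per cube (8-byte doubles, so round trips are bit-identical, with
a uint8 mask sidecar) or as a single RDS container.

## 2. The phantom generator

Real clinical cubes are not publicly available, so the package's tests
and examples run on parametric phantoms with known ground truth
(`phantom_params()`, `make_phantom_dataset()`).  A phantom is built
as follows:

* **Signatures.**  Each tissue class (skin, benign, malignant) has a
  smooth reflectance curve defined by control points and interpolated
  with a monotone Fritsch–Carlson spline, which cannot overshoot the
  `[0, 1]` control range.  The default curves are in-house fixtures
  chosen to *qualitatively* resemble dermoscopic tissue spectra —
  lesions darker than skin below 600 nm, the malignant class with a
  deeper 540–580 nm trough — and are **not** digitized from any
  measured dataset.
* **Mask.**  A single elliptical blob (radius 16–30% of the frame,
  eccentricity up to 0.6, low-order Fourier boundary perturbation)
  centered within the middle third of the frame, with lesion fraction
  constrained to 5–60% of pixels, emulating manual segmentations.
* **Cube.**  `mask * lesion_signature + (1 - mask) * skin_signature`,
  each component scaled by a mean-one log-normal per-image amplitude
  factor (sd 0.05, modelling illumination variability across
  acquisitions), plus i.i.d. Gaussian band noise (sd 0.02), then a
  spatial Gaussian blur (sigma 0.8 px, emulating optical blur and
  skin-texture correlation), clipped to `[0, 1]`.

Every cube derives its own seed from the dataset seed through a named
stream, so generation is fully deterministic and individual cubes can
be reproduced in isolation.  Default composition is 40 benign + 36
malignant, a realistic size for a single-site clinical collection.

What the phantoms do *not* emulate: radiative transfer in layered skin,
melanin/hemoglobin absorption physics, specular highlights, spatial
texture within lesions, camera-specific band correlation, or
inter-patient variability beyond a global amplitude factor.  A test
passing on phantoms therefore demonstrates that the machinery works and
that the GAN can recover a known, learnable structure — not that it
reproduces clinical data.  The phantom classes are deliberately
separable (a linear classifier on mean lesion spectra exceeds 95%
held-out accuracy, enforced by a test), because downstream
train-on-synthetic/test-on-real checks would be vacuous otherwise.

## 3. Architectures

The generator maps a 100-dimensional standard-normal latent vector
(DCGAN convention; the conditional variant appends the smoothed label
as one extra coordinate) through **exactly seven transposed-convolution
stages**: stages 1–6 are followed by batch normalization and ReLU, and
stage 7 by tanh, so outputs live in `[-1, 1]` (reflectance is mapped
affinely to that range, and back by `to_reflectance()`).  Stage 1
projects the latent vector to a 4×4 frame; stride-2 stages double the
frame to the smallest power of two covering the target; stride-1 filler
stages keep the count at seven; a final center crop reaches frames like
50×50 that stride-2 arithmetic cannot hit.  Channel widths start at
`base_width` (512 at full scale) and halve at each doubling.  When the
training cubes carry masks the generator emits one extra channel (116
bands + 1), binarized at the tanh midpoint 0 into a segmentation mask.

The discriminator mirrors this with **six convolution stages**: leaky
ReLU (slope 0.2) on stage 1, batchnorm + leaky ReLU on stages 2–5, and
a final convolution with kernel equal to the remaining frame followed
by a sigmoid, yielding one real/fake score in (0, 1).  In the
conditional variant the smoothed label is broadcast as one extra input
plane.  Condition values are affinely mapped to `[-1, 1]` on both
sides so the two class ranges sit symmetrically around zero at the
same scale as the latent coordinates and image channels.

## 4. Training recipe

Two phases, both Adam with betas (0.5, 0.999):

| parameter | RGB pretraining | hyperspectral cGAN |
|---|---|---|
| epochs | 100 | 200 |
| batch size | 128 | 2 |
| lr (G / D) | 2e-4 / 2e-4 | 1e-4 / 4e-4 (two time-scale) |
| equalized lr | off | on |
| label smoothing / 5% swap | on | on |
| L2 weight decay | 1e-5 | 1e-5 |

The adversarial step is the textbook non-saturating DCGAN update with
binary cross-entropy (the method specifies only the minimax game; BCE
is the standard instantiation): one discriminator update on the real
batch plus a generated batch with smoothed and randomly swapped
targets, then one generator update pushing its samples toward the
"real" target.  The two time-scale rule follows the cited convention
`lr_G < lr_D` (the source text is self-contradictory on the
direction; both rates are exposed in `train_config()`).  Equalized
learning-rate scaling multiplies each layer's weights by
`c = sqrt(2 / fan_in)` (`fan_in` = input channels × kernel area) at
every forward pass.  Raw weights are initialized so that the
*effective* (scaled) weights follow the DCGAN `N(0, 0.02)` convention:
unit-scale raw initialization would make the effective initial weights
He-sized, saturating the tanh output and, empirically, stalling
adversarial learning at these problem sizes, whereas the
reparameterization itself is unaffected (a property test verifies that
scaling raw weights by `k` while dividing the layer gain by `k` leaves
the forward pass unchanged).

RGB pretraining fits an unconditional 3-channel twin of the same
architecture on 50×50 RGB images.  `transfer_weights()` then copies all
interior layers verbatim into the hyperspectral model; in the
generator's output stage and the discriminator's input stage, the
parameter slices tied to the bands nearest 630/532/465 nm receive the
red/green/blue slices, and every other new-channel parameter (remaining
bands, mask channel, conditional label input) keeps its seeded random
initialization.  Pretraining keeps label smoothing and swapping on —
the stabilizers address discriminator overconfidence, which is present
in both phases.

The mask output channel is trained adversarially along with the bands
by default (the discriminator sees it as a 117th channel); an optional
per-pixel binary cross-entropy term against the real masks
(`mask_aux_loss`) is provided but off, since the method defines no mask
loss.

**Batch normalization at batch size 2.**  Running means/variances are
accumulated as a cumulative average until the exponential window
(momentum 0.1) takes over, so short runs still leave usable inference
statistics.  Generation nevertheless uses the statistics of the
generation batch itself (without updating the running averages) — the
standard choice for batch-normalized GAN generators, and the regime the
generator was optimized in.  One consequence worth knowing: a
batch-constant condition value contributes only a per-channel mean
shift, which batch statistics remove; class-conditioning comparisons
should therefore generate both classes *in the same batch* (as
`simulate()` does when given a mixed class vector).

## 5. Evaluation suite

* **Fréchet distance** between Gaussian fits `(μ, Σ)` of image
  embeddings: `||μ₁−μ₂||² + Tr(Σ₁+Σ₂−2(Σ₁Σ₂)^{1/2})`.  The matrix
  square root is computed via the symmetric form
  `sqrt(S1) Σ₂ sqrt(S1)`; eigenvalues above −1e−8 are clipped to zero,
  anything more negative is reported as a numerical error.  For
  116-band cubes there is no standard pretrained feature extractor, so
  the default embedding is deterministic and pretraining-free: per
  band, the spatial mean, spatial standard deviation, and
  lesion/background contrast (3B features, bit-reproducible).  An
  optional learned embedding uses the penultimate activations of the
  fidelity classifier.  **Absolute values from either embedding are
  not comparable to published Inception-based FID numbers.**
* **Jensen–Shannon divergence** between spectral signatures, with
  base-2 logarithms so the divergence is bounded by 1, `0·log 0 := 0`,
  and signatures L1-normalized first (reflectance profiles are not
  probability vectors; normalization makes the comparison
  shape-sensitive and scale-free).
* **Confusion-matrix metrics** (accuracy, precision, recall, F1) in
  percent, rounded to two decimals, with zero-denominator metrics
  flagged `NA` rather than raised as errors.
* **Fidelity protocol**: a compact residual classifier (3×3 stem, four
  residual blocks of widths w/2w/3w/3w with three stride-2 halvings,
  global average pooling, logistic output; default width 16) is trained
  from scratch, with Adam for up to 50 epochs and early stopping once
  training accuracy reaches 100%, *only* on synthetic cubes, then
  scored on the real set, which the trainer never receives.  Deliberate
  overfitting of the synthetic set combined with good real-set metrics
  indicates distributional overlap.  A from-scratch network replaces
  the original ImageNet-pretrained backbone so no external weights are
  required; this makes absolute protocol metrics conservative relative
  to a pretrained classifier.

## 6. Problem sizes used in the checks

The automated checks run at sizes chosen to exercise every code path
on a single CPU: unit tests use 8–16 px phantom cubes with 4–16 bands;
the adversarial end-to-end check trains on 76 cubes at 16×16×16 with
batch 2 and all stabilizers, logging the embedding distance every 10
epochs over a 100-epoch run (the untrained baseline must be beaten by
epoch 30, and class conditioning is assessed at the end of the run,
where it is reliably detectable); the fidelity-protocol check trains
the residual classifier on 1000 class-balanced phantoms at 24×24×16.
These sizes are the package's own reduced-geometry defaults for
continuous verification, not statements about full-scale behavior.

## 7. Known limitations

* Phantom realism is deliberately limited (Section 2); conclusions
  about clinical data require clinical data.
* Fréchet distances depend on the embedding; only differences under a
  fixed embedding are meaningful.
* Batch-2 adversarial training is noisy; the loss log should be
  inspected (`plot()` on the fit) before trusting a checkpoint.
* The conditional discriminator sees the label only as an input plane;
  with few epochs the generator may ignore its condition.  The
  class-conditioning test exists precisely to catch this.
* HDF5 containers are not supported in this implementation; the
  single-file container format is RDS, and ENVI covers interchange
  with other hyperspectral tools.
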