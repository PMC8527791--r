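---
title: "Predicting wheat physiological traits from leaf reflectance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting wheat physiological traits from leaf reflectance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spectratraits)
```

## The problem

Leaf hyperspectral reflectance — the fraction of light a leaf reflects at
each wavelength from 400 to 2400 nm — carries the optical signatures of
pigments, nitrogen-bearing proteins, water and leaf structure. Because
gas-exchange and destructive lab measurements of photosynthetic traits take
minutes to days per leaf, regression models that map a one-second reflectance
measurement to trait values are a key tool in crop phenotyping. This package
implements such a pipeline for ten wheat traits: LMA (g m⁻²), N~area~
(g N m⁻²), SPAD, N~mass~ (mg N g⁻¹), V~cmax~, V~cmax25~, J, A
(µmol m⁻² s⁻¹), g~s~ (mol m⁻² s⁻¹) and V~cmax25~/N~area~
(µmol CO₂ s⁻¹ (g N)⁻¹).

The centrepiece is a dilated 1D convolutional network trained with
multi-task learning, flanked by the classical chemometrics baseline (PLSR),
gradient-boosted trees, an MLP and a bidirectional LSTM, and a mean ensemble.
A synthetic leaf-spectra generator makes the whole pipeline trainable and
testable without access to any field dataset.

## Input handling and preprocessing

**CSV schema.** Spectra arrive as CSV: first column wavelengths in 1 nm
steps, first row observation names, one column per observation. The reader
caps the number of observations (default 100, configurable) to mirror
shared-service limits and fails loudly on malformed headers, non-1 nm grids
or duplicate names.

**Jump correction.** Multi-detector spectroradiometers leave step
discontinuities at detector boundaries (typically 1000 and 1800 nm; some
instruments 1830 nm). Vendors correct these in proprietary software without
published formulas, so the package defines its correction explicitly: for
each splice, the right-hand segment is shifted by a constant chosen so the
first difference across the splice equals the mean first difference of the
five points on each side. The offset is additive because the artifact is a
detector offset rather than a gain error; the method is idempotent and exact
for spectra locally linear at the splice (smooth leaf spectra are close to
that regime over an 11 nm window).

**Trimming and quality filtering.** The working range is the half-open
window \[400, 2400) nm, i.e. exactly 2000 wavelengths — chosen half-open so
the fixed network input length is a round 2000. Spectra whose reflectance at
800 nm falls outside the inclusive band \[0.35, 0.6\] are discarded as
measurement failures (a healthy wheat leaf has an NIR plateau in that band).

**Splitting.** Samples are assigned wholly to train/validation/test at
fractions 0.7/0.1/0.2 (floor rounding, remainder to train) under a stated
seed. A single shared split is used for all traits: a per-trait split is
incompatible with a multi-task model because a sample in one trait's training
set and another trait's test set would leak its spectrum into training.
Per-trait sample counts then vary naturally through the missingness mask.

## Model family

All neural models consume the 2000-point spectrum after average pooling with
window 10 (noise damping; output length 200).

The multi-task CNN is, in order: average pool 10; four dilated convolution
blocks (filter size 5, dilation 2, stride 1, "same" zero padding) with 75,
150, 225 and 300 filters, each followed by batch normalisation then ReLU;
flatten; fully connected 800 + ReLU + dropout 0.2; fully connected 200 +
ReLU + dropout 0.2; linear output of 10 traits. The single-task variant
differs only in its 1-unit output. A stack of stride-1 dilated layers sees
`1 + Σ (k−1)·d` inputs per output neuron — 13 for the two-layer
filter-5/dilation-1-then-2 illustration, 33 pooled positions for the default
stack.

Design points that were genuinely open and how they were fixed:

* **Padding**: "same" zero padding keeps the length fixed and is consistent
  with the zero-filled regions produced by spectral trimming.
* **Batch-norm placement**: convolution → batch norm → ReLU, the
  conventional order.
* **MLP**: reuses the pooled input and the CNN's fully-connected head
  (800/200, dropout 0.2) so the comparison isolates the value of the
  convolutional stack.
* **LSTM**: two stacked bidirectional layers with 100-dimensional hidden
  units over the pooled sequence; the concatenated final hidden states (200
  dims) feed a 200-unit ReLU layer and a single-trait output. The
  representation fed to the head is the conventional choice of final states.
* **Target scaling**: traits span three orders of magnitude (g~s~ ≈ 0.5 vs
  J ≈ 218), so each trait is z-scored using training-partition statistics
  and predictions are unscaled on the way out; without this the multi-task
  loss would be dominated by the large-valued traits.
* **Batch size**: not part of the published protocol; 32 by default.

PLSR (via mixOmics, NIPALS regression mode) and XGBoost are fitted per trait
on raw per-nm reflectance over a fixed wavelength range. PLSR's component
count is searched over 1–30 and the value maximising validation R² kept
(ties to fewer components); the direction "maximise" is deliberate — the
alternative reading of the protocol (minimising validation R²) would select
the worst model and is taken to be a typo. XGBoost hyperparameters come from
the fixed grid learning rate (0.01, 0.02, 0.05, 0.06, 0.08, 0.1) × max depth
(3, 5, 7, 9, 11) × column subsample (0.3, 0.5, 0.8, 1), ties toward
shallower trees; 100 boosting rounds (the round count is not part of the
published protocol). Four fixed-range PLSR models (\[400,900\], \[400,1000\],
\[400,1700\], \[400,2400\]) support narrower-range instruments;
`match_plsr_range()` picks the largest range an input covers.

The ensemble is the arithmetic mean of member predictions; its default
membership is the spectrally-trimmed multi-task CNN, the spectrally-trimmed
single-task CNNs and PLSR.

## Training protocol

Adam at learning rate 1e-4 for 1000 epochs, evaluating the validation
partition every 10 epochs and retaining the weights with the lowest masked
validation MSE (early stopping by checkpoint selection — training always
runs the full budget, and the best checkpoint typically occurs much
earlier). The loss is the per-trait masked mean squared error summed over
traits, the only form consistent with per-trait sample counts that differ
inside one model; a trait unmeasured for a sample simply contributes nothing
for that sample. Divergence (non-finite loss) aborts with a diagnostic
rather than silently propagating NaN.

Two augmentations, both exactly as in the reference protocol:

* **Horizontal shifts** (offline): the training partition is expanded by 50%
  with copies shifted by a uniformly random nonzero integer in \[−5, 5\] grid
  positions, edges replicated (at the reference 772 training samples this
  gives 1158). Shifts are read as integer 1 nm positions because the data
  live on an integer grid; a zero shift is excluded because an identical
  copy adds nothing.
* **Spectral trimming** (online, CNN-family only): for every presentation of
  every training sample a pair (low, high) is drawn — low ~ truncated
  N(400, 100²) on \[400, 700\], high ~ truncated N(2400, 500²) on
  \[1000, 2400\], pairs with span < 350 nm rejected and redrawn — and
  reflectance outside \[low, high\] is zeroed while the input length stays
  fixed. Rejection sampling is used because it preserves the stated
  marginals conditioned on the span constraint exactly. Trimming is never
  applied at evaluation time, and never to PLSR/XGBoost, whose fixed-range
  fits replace it.

Training is deterministic given the configuration seed and a fixed BLAS
thread count (platform-level, not cross-platform, determinism).

## Evaluation metrics

Per trait over the observed test pairs:

* **R²** = 1 − Σ(y−ŷ)²/Σ(y−ȳ)² — the coefficient of determination, which is
  negative when a model underperforms the mean predictor;
* **Abs(Bias%)** = |100·(mean(ŷ) − mean(y))/mean(y)|;
* **REP** = 100·RMSE/|mean(y)| — relative error of prediction.

The percentage metrics are the standard chemometrics definitions; their
exact published forms are not printed anywhere authoritative, so
reproduction of published bias/REP magnitudes on external data is not
guaranteed. Reported metrics are conventionally means over several seeds;
`aggregate_reports()` averages run reports.

## The synthetic generator

`generate_dataset()` emulates the structure of a wheat leaf-clip
reflectance campaign:

* **Traits** are drawn from a multivariate normal matched to the reference
  population's per-trait means and standard deviations, with a three-factor
  correlation structure (nitrogen/pigment, photosynthetic capacity,
  structure/water). The real inter-trait correlation magnitudes are reported
  in the primary field studies, not re-derived here; the factor loadings are
  plausible stand-ins that produce a block-correlated structure, which is
  what the multi-task experiments need. Marginals are normal at the
  reference moments (no distributional family is documented for the real
  population); small-valued traits are floored at 2% of their mean to stay
  physical.
* **Spectra** are rendered as a smooth leaf envelope — visible trough with a
  green peak at 550 nm, logistic red edge near 720 nm, NIR plateau, gentle
  SWIR decline, Gaussian water dips at 1450/1940 nm — whose features are
  linear functions of standardised trait scores: SPAD drives the visible
  level, N~area~ the red-edge position (5 nm per SD), LMA the plateau height
  and SWIR slope, g~s~ the water-band depths. The linkage echoes leaf
  optics qualitatively (pigment/nitrogen in the visible and red edge,
  structure and water in the NIR/SWIR) and is recorded in the returned
  ground truth so tests can verify recovery by regression. White noise
  (sd 0.002) is added; plateau coefficients are clamped so every non-outlier
  spectrum keeps R(800) inside \[0.35, 0.6\].
* **Artifacts**: a configurable fraction (default 2%) of spectra get a
  plateau outside the quality band (outliers the filter must catch), and
  additive detector steps (default +0.02 at 1000 nm, −0.01 at 1800 nm) are
  injected so jump correction is exercised end to end. Values are clipped to
  \[0, 1\] with a warning count.
* **Missingness** follows the reference per-trait sample counts (488–1013
  measured of 1013), applied at random per trait with the guarantee that
  every sample keeps at least one observed trait.

What the generator does **not** emulate: radiative-transfer realism
(PROSPECT-class leaf optics), instrument-specific noise spectra, genotype or
environment structure, and realistic correlation magnitudes between traits.
Passing tests on synthetic data therefore demonstrate that the pipeline's
machinery — preprocessing, augmentation, optimisation, early stopping,
evaluation — functions and recovers planted signal; they do not certify
accuracy on real wheat spectra.

## Problem sizes used by the test-suite and why

The default architecture has ~50M parameters (the flattened 300 × 200
feature map feeding 800 units dominates), which is a GPU-scale training job.
The package's tests and examples therefore train a **desk profile** —
`cnn_config(preset = "desk")`: channels 12/24/36/48 and fully connected
128/64, with pooling, filter size, dilation, batch norm, ReLU and dropout
identical to the default — on synthetic datasets of a few hundred samples
for 200 epochs. These sizes were fixed from parameter/FLOP counts as the
largest configuration a single CPU trains in minutes; the desk-scale checks
(test R² ≥ 0.8 on the strongly planted traits LMA and N~area~ for the CNN,
≥ 0.7 for tuned PLSR on the same near-linear signals) are calibrated to that
profile. Two smaller property checks deviate from protocol defaults for
stated reasons: the noiseless-recovery check disables dropout and the shift
augmentation (a ±5 nm shift aliases the red-edge position, which *is* the
planted N~area~ signal) and raises the learning rate to 3e-4 to reach
convergence in a small network; the multi-task-versus-single-task comparison
runs in the small-sample, high-label-noise regime where single-task models
overfit, because the shared-trunk advantage is a noise-averaging effect and
is not expected to appear in an underfitting regime.

## Known limitations

* Exact (1e-9) removal of a planted splice step holds where the spectrum is
  locally linear at the splice; on curved spectra with noise the residual is
  bounded by local curvature and noise, not zero.
* The LSTM trains slowly on CPU (sequential backpropagation through 200
  timesteps in R) and exists primarily as a comparison point, as in the
  reference study, where it was the weakest model.
* Bias% and REP definitions are stated above; other definitions circulate in
  the chemometrics literature.
* Fixed-range PLSR models require true coverage of their range and refuse
  zero-filled gaps; only the CNN-family models accept arbitrary-coverage
  input (zero-filled), consistent with how they are trained.
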