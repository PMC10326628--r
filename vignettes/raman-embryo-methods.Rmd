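---
title: "Methods: Raman metabolomics of spent embryo culture medium"
author: "ramanEmbryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman metabolomics of spent embryo culture medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanEmbryo)
```

## The problem and the data model

A day-3 cleavage-stage embryo conditions the droplet of culture medium it
grows in: amino acids are consumed or released, and the spent droplet's
composition carries a metabolic signature of the embryo's developmental
potential. Raman spectroscopy reads that signature non-invasively as a
vibrational fingerprint over roughly 600–1800 cm⁻¹. The analysis task is
twofold: (i) relative quantification of individual amino-acid markers
between samples that did and did not lead to pregnancy after transfer, and
(ii) supervised prediction of that outcome from the whole spectrum.

The package's unit of data is a `raman_spectrum`: a strictly increasing
shift axis (cm⁻¹) with one intensity per channel plus acquisition metadata.
A cohort couples several replicate spectra (five, in the emulated design)
to one biological sample; outcome labels attach to samples, never to
individual spectra, and every split, fold and test respects that grouping.

## The synthetic cohort generator

Clinical spectra of this kind are not publicly deposited, so the package
generates cohorts with known ground truth (`generate_cohort()`). Each
spectrum is built as

* Gaussian bands (FWHM 12 cm⁻¹, a typical solution-phase linewidth; no
  lineshape is dictated by the data model, and a pseudo-Voigt would change
  nothing structurally) at the catalog positions: seven amino-acid marker
  bands, the phenylalanine internal-standard band at 1003 cm⁻¹ (the most
  intense signal, mean amplitude 120 intensity units), and seven
  group-insensitive matrix bands that fill out the fingerprint;
* per-sample band amplitudes drawn `N(mean, sd)` and truncated at zero,
  with planted group effects expressed as standardized mean differences:
  for an effect `d`, the non-pregnancy mean is shifted by `d · sd`. The
  default plants `d = 1` on tyrosine, tryptophan and serine, the markers
  reported elevated in non-pregnancy media; means (35–55 units) sit far
  enough from zero that truncation is negligible;
* multiplicative log-normal replicate jitter (σ = 0.05) on every band
  amplitude, mimicking acquisition-to-acquisition variation;
* a smooth background that dominates the raw signal, as fluorescence does
  in practice: a random gentle 4th-order polynomial plus a broad
  exponential hump decaying from the low-shift end (magnitude 800 units
  against band amplitudes of tens of units);
* white Gaussian noise (sd 3 for the `p532` preset) and a Poisson number
  (rate 0.2/spectrum) of cosmic-ray spikes, 1–3 channels wide and 5–20×
  the local signal;
* the `p785` platform preset halves band amplitudes and planted effects
  and doubles the noise, emulating the weaker contrast of liquid-sample
  acquisition against crystalline-sample acquisition. Neither platform's
  absolute intensity scale or SNR is documented anywhere we could anchor
  to, so these presets are stated choices, not fits.

The generator's ground truth records every sample's label and amplitudes,
every spectrum's effective (jittered) band amplitudes, its injected
baseline curve and its spike channels — the oracles used throughout the
test suite. Class labels are assigned at the sample level with
deterministic rounding of the class balance (default 54/107
non-pregnancy), and identical configurations reproduce cohorts bit for
bit.

What the generator does **not** emulate: instrument response and wavenumber
calibration error, substrate (SERS) enhancement physics, correlated
(pink/structured) noise, water background, and between-patient clinical
covariates. Tests passing on synthetic cohorts therefore demonstrate the
correctness and statistical behaviour of the pipeline, not clinical
performance on real spectra.

## Preprocessing chain

Stages run in a fixed order: despike → clip → smooth → baseline-correct →
normalize. All parameters live in `preprocess_config()`.

**Despiking.** Channels whose residual against a rolling median (window
11) has a modified z-score above 8 form candidate runs; runs of at most 4
channels are candidate spikes. A run is confirmed only if it also towers
over the linear interpolation of its flanks — by more than `8 · scale` and
by more than 50% of the local signal level. The second condition is what
separates a genuine narrow band top from a cosmic spike: the sharp
phenylalanine band at 1003 cm⁻¹ produces 1–2-channel runs whose z-scores
can exceed any reasonable threshold, but it only exceeds its own flanks by
a few percent, while cosmic spikes are several-fold excursions. Confirmed
runs are replaced by the flank interpolation; every other channel is
returned bit-identical. Genuine bands narrower than ~5 channels FWHM on a
flat background would be at risk, but no band in the fingerprint catalog
is that narrow.

**Band clipping** keeps 600–1800 cm⁻¹ inclusive (1201 channels on a
1 cm⁻¹ axis).

**Savitzky–Golay smoothing** (window 11, order 3, via `signal::sgolayfilt`)
preserves polynomials up to order 3 exactly — the suite checks
reproduction of a cubic to 1e-9 — and the window is short enough not to
flatten 10–12 cm⁻¹ bands. Both parameters are exposed; nothing in the
emulated design fixes them.

**SNIP baseline.** Intensities are compressed with the
log-log-square-root (LLS) transform, clipped against the symmetric
two-point average with a half-window decreasing from 60 down to 1, and
transformed back. The decreasing window reduces peak erosion relative to
the increasing-window variant. Two contracts hold to numerical tolerance
and are asserted in the tests: the baseline never exceeds the signal, and
`corrected + baseline` reconstructs the input exactly. On the generator's
peakless backgrounds the residual after correction is under 5% of the
baseline maximum; a 50-unit band on a flat 100-unit background is
recovered within 10% and the off-band baseline within 5%.

**Normalization** is per-spectrum min–max to [0, 1] over the clipped band,
so every spectrum attains both bounds exactly. Quantification ratios are
unaffected because the baseline-corrected minimum is essentially zero,
making the map a pure scaling.

One property worth knowing: the chain is *not* idempotent. Re-running it
on its own output changes the result by ~0.1 RMS (on the [0, 1] scale),
dominated by a second round of SNIP erosion of broad corrected structure
and secondarily by re-smoothing; despiking and clipping are exact fixed
points on preprocessed output. The suite pins these bounds.

**Outlier screening** (`detect_outlier_spectra()`) operates on the
preprocessed batch: squared Mahalanobis distance in the first 3 PC scores
against the χ²(3) 0.999 quantile. The criterion for "abnormal" spectra is
not dictated by the emulated design beyond the fact that some were
removed; PCA–Mahalanobis at a reportable quantile is the standard choice.
A sample disappears only if all its replicates are rejected. With planted
group structure the score distribution is a two-component mixture, so the
χ² calibration is conservative (fewer rejections than nominal), which the
clean-batch test reflects (≤ 1–2% rejected).

## Internal-standard quantification

The expression value of an analyte in a spectrum is the maximum intensity
in a ±5 cm⁻¹ window around its assigned band; the quantification value is

$$Q = \log_{10}\!\frac{I_{\mathrm{target}}}{I_{\mathrm{standard}}}$$

against the phenylalanine 1003 cm⁻¹ band. Choices made where the method
statement leaves freedom, all surfaced as arguments:

* **log base 10** (a decade of relative intensity = 1 unit); the base is
  configurable.
* **in-window maximum** rather than a fitted area: the simplest faithful
  reading of "peak intensity", and the ±5 cm⁻¹ window absorbs the
  1–2 cm⁻¹ position doublets quoted for several bands. Serine's marker at
  1326 cm⁻¹ comes from the quantification description itself rather than
  the general assignment table, and is taken as authoritative.
* **Mann–Whitney U** (normal approximation, no continuity correction, so
  identical groups give p = 1 exactly) as the default group test — the
  original figure does not name its test, and a rank test is robust on
  bounded normalized intensities. A Welch t-test sits behind
  `test = "welch"`.
* **per-spectrum observations** by default, mirroring the presentation of
  all spectra as metabolic observations; `per_sample = TRUE` aggregates
  replicates first. Replicates of one sample share its amplitude draw, so
  per-spectrum testing treats correlated observations as independent and
  inflates the effective sample size — fine for exploration, but the
  package's own power/type-I simulations use one replicate per sample to
  keep the test exact.
* **no multiplicity adjustment** across the seven analytes by default
  (matching the seven separately reported tests); `p_adjust = "BH"` is
  available.

Noise-free generator cohorts run through the *full* preprocessing chain
recover every ratio within 0.02 of `log10(A_analyte / A_phe)` computed
from the ground-truth amplitudes; this is pinned in the acceptance suite.

## Feature extraction and classification

PCA is fit mean-centered and variance-unscaled (channels share units after
normalization) on the training partition only — whether the original
analysis fit PCA before or after splitting is not stated, and fitting on
all data would leak test information into the features. Components carry a
deterministic sign convention (largest-magnitude loading positive);
exploratory summaries of the first three components (histograms plus
Silverman-bandwidth kernel densities per outcome group) come from
`summarize_components()`, and classifiers consume the first 100 scores by
default (clipped to the matrix rank with a warning when the cohort is
small).

`make_split()` performs the 4:1 stratified sample-level split.
`grid_search_cv()` evaluates a hyperparameter grid by group-aware
stratified k-fold CV (default 5 folds; the fold count is not dictated),
selects by mean CV accuracy with ties to the first-listed point, and
refits on all training data. The four families:

* **1D CNN** — implemented in base R matrix algebra because no
  deep-learning framework is part of the package's dependency set: blocks
  of valid convolution (width 7, stride 1) → ReLU → max-pool 2, a dense
  ReLU layer (64 units), softmax head, cross-entropy loss, Adam
  (lr 1e-3), minibatch 32, default 40 epochs, optional early stopping on
  a validation loss. The grid covers {1, 2} convolution blocks and
  {8, 16, 32} first-block kernels (the second block doubles the count).
  Backpropagation is verified against central-difference numerical
  gradients in the test suite. Inputs are standardized internally and the
  scaling is stored with the model.
* **SVM** (`e1071`): radial and linear kernels, C ∈ {0.1, 1, 10},
  γ ∈ {default = 1/p, 0.01, 0.001}.
* **Random forest** (`randomForest`): the library exposes tree size
  through `nodesize`/`maxnodes` rather than a depth parameter, so the
  grid is trees {100, 300} × nodesize {1, 5} × maxnodes {unlimited, 32}.
* **XGBoost**: rounds {100, 300}, depth {3, 6}, learning rate
  {0.1, 0.3}, subsample {0.8, 1.0}.

Every stochastic fit is seeded from the spec seed plus the fold index, so
fixed configurations reproduce identical models and predictions.
Prediction returns probability pairs summing to 1; the hard label is the
argmax with exact ties resolved to non-pregnancy (the conservative call).
Evaluation is per-spectrum by default — blind-test counts are spectra —
with `aggregate_by_sample()` available for majority voting over a sample's
replicates (ties again to non-pregnancy).

## Evaluation

`eval_metrics()` reports per-class precision, recall, F1 and the per-class
accuracy — which is deliberately labelled "per-class accuracy (recall %)"
because that is what a per-class accuracy column in a two-class confusion
table arithmetically is (e.g. 31/45 = 68.89%). Overall accuracy is
trace/total and equals the class-frequency-weighted mean of recalls;
printing rounds to two decimals but the stored values are exact. ROC uses
pregnancy as the positive class (switchable); the threshold sweep advances
diagonally through tied scores, so the trapezoid AUC equals the
Mann–Whitney pair statistic with half-credit ties and is invariant under
monotone score transforms — both verified against brute-force pair
counting and against an independent ROC implementation.

## Simulation design behind the stochastic tests

The stochastic acceptance suite uses three scaled designs, chosen as the
smallest sizes at which the tested property is statistically decidable:

* **Recovery**: 50 cohorts of 200 samples × 1 replicate with d = 1.0 on
  tyrosine/tryptophan/serine; all three must be flagged at α = 0.05 with
  positive direction in ≥ 80% of cohorts. One replicate per sample keeps
  the rank test's nominal level exact (no pseudo-replication), and at
  n = 100 per group a d = 1 shift is detected essentially always.
* **Type-I control**: 200 null cohorts of 60 samples × 1 replicate;
  per-analyte rejection counts must lie within binomial bounds around 5%
  (Bonferroni-adjusted across the seven simultaneous per-analyte checks)
  and the pooled rate within plain 95% bounds. Testing seven analytes
  against unadjusted individual 95% bounds would spuriously fail ~30% of
  the time even for a perfectly calibrated test.
* **Classifier sanity**: on strongly separated synthetic score clusters
  every family must reach ≥ 0.9 blind-test accuracy, and with permuted
  training labels must average chance-level accuracy. The separable
  construction shifts both a feature subset and the whole vector: tree
  learners key on strong marginal splits while the convolutional net pools
  over feature positions, and the combined shift gives both kinds of
  learner the signal the construction promises.

## Known limitations

* The CNN is a compact reference implementation tuned for hundreds of
  spectra and ~100 features; it is not a performance-engineered framework.
* SNIP erodes very broad genuine structure (> ~120 channels at the default
  60 iterations); raise `snip_iterations` cautiously.
* Per-spectrum group testing with replicated samples is anticonservative
  (see above); use `per_sample = TRUE` when replicates are present and
  inference matters.
* Synthetic-cohort classifier accuracies characterize the pipeline on the
  generator's assumptions; they are not estimates of clinical accuracy.
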