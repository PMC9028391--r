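---
title: "Classifying thyroid FNA needle washes from MALDI-MSI pixel spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying thyroid FNA needle washes from MALDI-MSI pixel spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

MALDI mass spectrometry imaging turns one cytological slide into a raster of
mass spectra: each 50 µm pixel carries an intensity profile over the
3000–15,000 m/z protein range. `thyromsi` models the diagnostic question as
a three-class problem at the *pixel* level — hyperplastic thyrocytes (HP),
Hashimoto-thyroiditis inflammatory background (HT), and papillary thyroid
carcinoma (PTC) — and aggregates pixel-level class membership into a
*per-nodule* benign/malignant call. The modeling assumptions are:

1. Each phenotype has a characteristic set of protein peaks; mixtures occur
   between pixels (a nodule contains regions of different phenotypes), not
   within a pixel.
2. A multinomial logistic model with an L1 penalty on the ROI-average
   feature matrix selects a sparse peak signature able to separate the
   three phenotypes. The penalty is selected by stratified 5-fold
   cross-validation maximizing classification accuracy.
3. A nodule is malignant when enough of its evidence is malignant. Three
   aggregation rules operationalize "enough": the class of the overall
   average spectrum; at least one third of annotated ROIs called PTC
   (inclusive boundary, per the wording "at least"); and the fraction of
   PTC pixels strictly above a cutoff estimated on the training set by
   maximizing the Youden index J = sensitivity + specificity − 1.
4. A three-level triage refines the pixel rule: fractions below a lower
   cutoff are benign, above the upper cutoff malignant, and the closed band
   in between is a "gray zone" routed to follow-up rather than to a binary
   call. The defaults (7.0% and 16.7%) are exposed as configurable
   constants in `diagnosis_thresholds()`; 16.7% is also the default binary
   pixel cutoff.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mz_min`, `mz_max`, `mz_step` | 3000–15000, 1 Da | Da | linear-positive acquisition window; a fixed common grid since features are binned anyway |
| `smoothing_half_window` | 10 | grid points | quadratic Savitzky–Golay; standard MALDI practice |
| `baseline_iterations` | 100 | iterations | SNIP clipping depth; removes the slowly-varying chemical baseline |
| `normalization` | TIC | — | equalizes pixel ion yield; intensities sum to 1 |
| `peak_snr_threshold` | 3 | × MAD | local maxima below this signal-to-noise are discarded |
| `bin_tolerance` | 0.002 | relative m/z | peaks within ~10 Da at 5000 Da merge into one feature |
| `cv_folds` | 5 | — | penalty selection and internal accuracy assessment |
| `pixel_cutoff_high` | 0.167 | fraction | binary malignancy cutoff for the pixel rule (strict >) |
| `pixel_cutoff_low` | 0.070 | fraction | lower edge of the gray zone (strict <) |
| `roi_cutoff` | 1/3 | fraction | minimal share of malignant ROIs (inclusive ≥) |

## What the synthetic generator emulates

The generator stands in for clinical cohorts that are not publicly
deposited. It reproduces the *statistical structure* the analysis assumes:

- **Templates.** Each class is a set of Gaussian peaks (σ = 2 Da at
  5000 Da, scaling linearly with m/z, similar to linear-mode broadening).
  A configurable fraction of peaks is shared by all classes, the two benign
  classes share additional peaks with each other, and each class keeps at
  least one private peak. Any unimodal peak shape would serve equally.
- **Noise.** Exponentially decaying baseline, additive truncated-at-zero
  Gaussian noise, per-peak log-normal intensity jitter, and whole-peak
  dropout.
- **Mixtures.** A malignant nodule carries PTC on a fraction of its
  informative pixels and a benign background on the rest: 0.9 in the
  training design (training carcinomas are selected for high tumor
  content) and 0.5 in the validation design (validation nodules carry
  tumor cells in an otherwise benign background, the mechanism behind
  pixel-rule false negatives). Borderline histologies (FA, NIFTP, WDT-UMP)
  receive a 0.15 PTC admixture so they share features of both groups.
- **Cellularity.** The grade maps to the fraction of informative
  (template-bearing) pixels, drawn uniformly per nodule: poor 0.20–0.30,
  good 0.30–0.70, optimal 0.70–1.00. Background pixels carry baseline and
  noise only.
- **Design margins.** The default manifest fixes 70 training nodules
  (40 HP + 10 HT + 20 PTC, all good/optimal) and 170 validation nodules
  (33/77/19/41 across TIR2–TIR5; 105 benign / 65 malignant; 29 borderline;
  72 adequate-cellularity split 17/23/9/23). Pixel data are generated
  lazily per nodule from hierarchically split RNG streams, so manifests are
  byte-reproducible and adding nodules never perturbs earlier ones.

What it does **not** emulate: real spectral chemistry (hemoglobin
interference, matrix clusters, mass-calibration drift), spatial
autocorrelation of noise, pathologist variability in ROI annotation, and
the true overlap structure of clinical phenotypes. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* is correct and
well-behaved under its stated assumptions — not that the classifier's
clinical operating characteristics transfer to real FNAs.

## Numerical choices

- **Candidate cutoffs** for the Youden and double-cutoff estimators are
  midpoints between consecutive distinct observed fractions plus sentinels
  beyond the extremes, so the strict ">" rule is unambiguous at every
  candidate. Youden ties return the smallest maximizing cutoff. The double
  cutoff takes `high` as the smallest candidate maximizing the specificity
  of the malignant call (fraction > high) and `low` as the largest
  candidate ≤ `high` maximizing the sensitivity of the benign call
  (fraction < low); on well-separated data the two coincide and the gray
  zone is empty, and with no signal the gray zone spans the observed range.
- **Penalty selection.** Among penalties tying at the maximal
  cross-validated accuracy, the largest (sparsest) wins. One refinement: at
  the head of the penalty path the fold fits can carry active features
  while the full-data fit is still null, so the tie set is first restricted
  to penalties whose full-data fit attains the maximal training accuracy
  within the set. Away from this path-head artifact the rule is exactly
  "max CV accuracy, ties → larger penalty".
- **Standardization.** Features are standardized to unit variance before
  penalization; coefficients are stored on the standardized scale together
  with the centering/scaling constants, and raw-scale equivalents are
  derived for prediction, so an all-zero feature row scores as the
  intercepts alone.
- **Tie-breaking in class calls** is deterministic with PTC > HT > HP
  priority, so an exact tie never silently favors a benign class.
- **Degenerate inputs.** Pixels that are empty after trimming or have zero
  total ion current are excluded from every denominator and counted;
  nodules with no retained pixels or no ROIs receive an explicit
  "inadequate" verdict rather than a call. Metrics with zero denominators
  are reported as undefined (`NA`), never as 0. Constant features are
  dropped with a warning before fitting.
- **Preprocessing is not idempotent.** Savitzky–Golay smoothing is not a
  projection and SNIP continues to clip on a second pass, so re-running the
  chain changes a peaked spectrum by a few percent (less than the first
  pass by an order of magnitude on smooth peaks). The test suite asserts
  this near-stationarity rather than exact idempotence.
- **Percentage formatting** uses two-stage half-up rounding (to hundredths,
  then to one decimal), the convention of common clinical reporting
  workflows; `pct_round(100 * 87/126)` is 69.1, not 69.0.
- **Exact intervals** are Clopper–Pearson via the beta-quantile
  formulation, with the boundary conventions low = 0 at k = 0 and high = 1
  at k = n. They are conservative: their true coverage exceeds the nominal
  95% (at n = 30, p = 0.7 the exact coverage is 97.4%).

## Design choices where the design was open

- The feature bins are learned from the *training ROI-average* peaks only
  and frozen before any validation unit is touched, to prevent leakage into
  the feature axis.
- Averaging (ROI and overall) happens *after* per-pixel preprocessing, so
  TIC normalization equalizes pixel weights within an average.
- ROI overlap within a sample is an error, not last-wins: silent
  double-counting would bias the one-third ROI rule.
- Class imbalance in the training ROIs is left unweighted; the HT class is
  expected to under-perform relative to HP, which is acceptable because
  both map to the same benign binary call.
- The per-nodule pixel count defaults to 500 in the full-size analyses run
  by `scripts/acceptance.R` and the test suite. Clinical rasters are an
  order of magnitude larger; 500 pixels per nodule keeps a 240-nodule
  cohort tractable on a single core while leaving the per-nodule fraction
  estimates accurate to ~±2 percentage points.
- The noise model's defaults (baseline amplitude 8 decaying at 1/2000 per
  Da, additive SD 1 against peak heights of 40–120, 15% intensity jitter,
  3% dropout) describe a clean linear-mode acquisition; degradation
  scenarios are expressed by raising the additive noise or lowering the
  cellularity grade, not by changing the template chemistry.

## Known limitations

- The MAD-based noise estimate is computed on the baseline-subtracted,
  zero-clamped spectrum; at very low SNR it under-estimates the noise and
  the default threshold of 3 admits noise maxima. Raising
  `peak_snr_threshold` is the intended control; the single-linkage binning
  can otherwise chain dense noise peaks into wide features.
- The classifier is a linear model on binned peak intensities; it cannot
  represent nonlinear phenotype signatures, and probabilities under the
  cross-validated penalty are shrunk toward uniformity (calls are reliable
  before probabilities are).
- Only three spectral phenotypes are modeled; medullary carcinoma and
  other rare entities are represented through the PTC template in the
  synthetic design, as distinct templates are out of scope.
- imzML support covers the common continuous/processed layouts written by
  this package (external binary arrays, float64 m/z, float32 intensities,
  no compression); exotic vendor variants are not parsed.
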