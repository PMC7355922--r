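---
title: "Methods: Raman spectral classification for melanoma biopsy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman spectral classification for melanoma biopsy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most pigmented skin lesions biopsied during melanoma screening turn out to be
benign nevi. The number needed to treat (NNT, also number needed to biopsy) —
biopsied lesions per histologically confirmed melanoma — runs from about 6 to
30 in typical screening settings, i.e. 83.3–96.7% of biopsies find no
melanoma (`100 * (1 - 1/NNT)`). A non-invasive "second opinion" that keeps
sensitivity at 100% while raising specificity directly lowers the NNT.

This package implements a complete analysis pipeline for that decision
problem using in vivo Raman spectra of lesions: spectral preprocessing,
PCA + logistic-regression classification under leave-one-lesion-out
cross-validation (LOLOCV) with an exhaustive principal-component subset
search, lesion-level ROC/NNT evaluation, and a label-randomization null.
Because no clinical spectra are distributed with the package, a synthetic
cohort generator reproduces the statistical structure the analysis assumes,
so every stage is exercised end to end by the tests and the `analysis/`
scripts.

## The synthetic cohort generator

Spectra are hierarchical mixtures of eight tissue-constituent basis spectra
(collagen, triolein, ceramide, keratin, elastin, melanin, DNA, water), each
rendered as a sum of Gaussian peaks at standard Raman band assignments
(CH2/CH3 deformation ~1440–1450 cm⁻¹ for lipids; Amide III ~1250–1270 cm⁻¹
and proline/hydroxyproline 855/940 cm⁻¹ for collagen; phenylalanine
1003 cm⁻¹; a broad melanin 1380/1580 doublet; the ~1640 cm⁻¹ OH bend) and
normalized to unit trapezoid area. Peak tables live in configuration
(`default_constituent_bases()`), not in code.

The hierarchy mirrors how multiple measurements on one lesion vary
biologically: lesion-level mixing weights are Gaussian around per-class means
with relative dispersion `weight_cv` (default 0.25), and each measurement
jitters them again with `intra_lesion_cv` (default 0.10), both truncated at
zero. The planted class difference has two parts:

* **weights** — melanoma has more collagen and DNA and less triolein
  (`default_class_weight_means()`); the reduced-lipid direction is enforced
  by the configuration validator;
* **band shift** — melanoma collagen peaks in the Amide III region
  (1230–1300 cm⁻¹) are shifted by `amideIII_shift` (default +10 cm⁻¹).

The shift is a deterministic class marker, so at the default settings the
classes are separable nearly perfectly once noise is removed; the default
cohort is deliberately an *easy* recovery target (best-subset AUROC close
to 1), with the weight overlap and the measurement hierarchy still providing
realistic within-class structure. The null configuration
(`null_synthetic_config()`) equalizes the class means and zeroes the shift,
making labels independent of spectra by construction.

On top of the clean mixture (scaled by `signal_scale = 5e4` counts·cm⁻¹,
giving Raman peaks of order 100–200 counts) the generator plants exactly the
artifacts the preprocessing chain removes:

* an order-5 polynomial fluorescence baseline in the wavenumber coordinate
  rescaled to [-1, 1] (numeric conditioning), with coefficients drawn from
  `default_baseline_ranges()` and shifted to be non-negative — the constant
  term (600–1500 counts) dominates, so fluorescence is 5–15× the Raman
  signal, as in tissue;
* i.i.d. Gaussian noise (`noise_sd = 4` counts, a shot/dark-noise stand-in);
* Poisson-count cosmic-ray spikes, one grid point wide, at
  `cosmic_ray_rate = 0.3` per spectrum with amplitudes 5–20× the spectrum
  maximum.

Cohort structure defaults match the study design the pipeline targets: 53
pigmented lesions and 7 melanomas over 52 patients (lesions assigned
round-robin, so 8 patients carry two lesions), 2–6 measurements per lesion
with per-class count distributions whose means (~2.96 and ~3.85) give
expected totals of about 158 pigmented and 27 melanoma measurements, and a
1980-point grid over 800–1790 cm⁻¹. The per-lesion measurement-count
distribution beyond "at least two, more for larger lesions" is an assumption
recorded in configuration. One RNG stream per cohort is derived from
`seed`, with per-lesion sub-streams, so a cohort regenerates stably.

What the generator does **not** emulate: instrument response drift, detector
nonlinearity, wavenumber miscalibration (only an affine read-time hook is
provided), patient-level correlation beyond lesion assignment, and the true
diversity of melanocytic lesions. Passing tests therefore demonstrate that
the pipeline recovers *planted* structure under *modeled* artifacts — not
clinical performance.

## Preprocessing

`preprocess_dataset()` applies, per spectrum and in this order: optional
dark-spectrum subtraction; cosmic-ray removal; Savitzky–Golay smoothing;
modified-polynomial baseline subtraction; optional intensity-response
correction; cropping to 800–1790 cm⁻¹ (inclusive); area normalization
(trapezoid area scaled to 1, which marks the spectrum `preprocessed`).
Smoothing precedes baseline removal, and response correction follows it;
both orders were genuinely open and are fixed here (and tested) as listed.
Because every stage is linear or scale-equivariant and normalization comes
last, the full chain is invariant to positive rescaling of the raw counts —
a property the tests check to machine precision.

Parameter choices:

* **Cosmic-ray removal** — the step is standard but no algorithm is
  canonical; this package flags points where the residual from a running
  median (window 5) exceeds 8× a robust scale, then repairs them by linear
  interpolation of the nearest clean neighbours (nearest-neighbour extension
  at the edges). The robust scale is the MAD of the residuals floored at
  0.1% of the spectrum's dynamic range: without the floor, a noiseless
  smooth spectrum (MAD ≈ 0) would be mass-flagged at its peaks. If more than
  5% of points would be flagged the spectrum is returned unchanged with a
  warning flag — that density is not cosmic rays.
* **Smoothing** — Savitzky–Golay, window 11, order 3: on the 0.5 cm⁻¹ grid
  the window spans ~5.5 cm⁻¹, well under the ~19 cm⁻¹ instrument FWHM the
  band widths reflect, so peaks are preserved while the filter is exact on
  cubic trends (tested, including the asymmetric end frames).
* **Baseline** — iterative modified polynomial fitting (Lieber-style):
  fit an order-5 least-squares polynomial, clamp the data to the fit from
  above, refit; stop when the maximum relative change of the fit drops below
  1e-4 or after 100 iterations (non-convergence returns the last iterate
  with a flag, never an exception). The order is fixed at 5; the stopping
  rule is this package's choice since the iteration is standard but no
  tolerance is. A pure order-5 polynomial is a fixed point (tested at 1e-6
  relative).

**Known limitation:** a fifth-order polynomial cannot distinguish
fluorescence from genuinely broad Raman structure. On artifact-free
noiseless cohorts the chain returns the pure mixtures within ~1.5% RMS when
only narrow-band constituents are present, but absorbs part of the
~100 cm⁻¹-wide melanin and water bands (distortion up to ~9% RMS at default
weights). Both regimes are pinned by tests. Under the planted order-5
baseline the fit recovers the true baseline to well under 2% of the baseline
RMS (tested over 100 seeded spectra).

## Classification

PCA is fit by mean-centered SVD on the area-normalized spectra — centering
only, no per-wavenumber variance scaling, which is standard for normalized
spectra. Components use a deterministic sign convention (largest-magnitude
loading positive) and are ordered by explained variance.

Cross-validation leaves out one *lesion* (all its measurements) per fold.
PCA is refit on each fold's training spectra and the held-out spectra are
projected with the training rotation; nothing about the held-out lesion
enters the fit (a leakage test perturbs held-out spectra and asserts the
training scores are unchanged). Because PCA is label-free, the per-fold
projections are computed once (`lolo_fold_scores()`) and reused across all
candidate subsets and all label permutations; the cache is asserted equal to
naive refitting at 1e-10.

The candidate models are logistic regressions on every subset of the first
15 PCs with at most 6 members — 9,948 subsets, the size-6 cap being the
one-in-ten rule at 60 lesions. Every measurement carries its lesion's label
and all measurements are weighted equally. Two numerical choices matter:

* **Ridge penalty, `reg = 1e-4`** — a plain logistic fit diverges under
  perfect separation, which is common with ~180 training spectra and
  well-separated classes; a tiny quadratic penalty on the coefficients
  (intercept unpenalized) guarantees a finite optimum while leaving
  probability rankings essentially untouched. Fits use Newton's method with
  step halving to a gradient infinity-norm below 1e-8, in compiled code
  because the subset search performs ~600,000 such fits.
* **Score standardization** — PC scores of unit-area spectra are of order
  1e-3, on which a fixed penalty of 1e-4 would be enormously stronger than
  on O(1) features: the fit collapses toward the intercept, and
  leave-one-lesion-out then produces *anti*-predictive posteriors (holding
  out a melanoma lowers the training prevalence and hence the held-out
  probability). Scores are therefore divided by their training-fold standard
  deviations (held-out scores use the training SDs — no leakage) before the
  logistic stage, making the penalty scale-free. Whether the original
  analysis standardized scores is unknowable from the outside; this package
  standardizes, and documents it as its own choice.

A lesion's posterior is the maximum over its measurements' probabilities.
This is exactly the per-lesion OR rule — call a lesion cancerous if any
measurement is called cancerous — at every threshold, a threshold-wise
equivalence the tests check exhaustively on toy sets with ties. The
best subset maximizes the lesion-level AUROC; ties within 1e-12 resolve to
the smallest subset, then lexicographically (several subsets routinely tie,
so the rule is needed for determinism).

## Evaluation

The ROC treats each lesion as one observation. Thresholds are the unique
posteriors in descending order behind a +Inf sentinel, and a lesion is
called melanoma when its posterior is ≥ the threshold — ties are
biopsy-recommended, the conservative direction for screening. The AUROC is
the trapezoid area, identical to the tie-corrected Mann–Whitney statistic
(property-tested on 1,000 random posterior sets, and cross-checked against
pROC). The confidence band is a stratified percentile bootstrap over lesions
(2,000 replicates by default, seeded); stratification guarantees both
classes in every replicate. The band method is this package's choice.

The screening operating point fixes sensitivity at 100% — the threshold is
the minimum melanoma posterior — and reports the best specificity achievable
there (tested as a supremum against an exhaustive threshold sweep). From the
confusion counts: `nnt_before = total lesions / melanomas`,
`nnt_after = recommended biopsies / melanomas detected`,
`biopsies_avoided = 100 · TN / (TN + FP)`. Values are stored at full
precision and displayed to one decimal.

## Randomization null

With 7 melanomas in 60 lesions, a high AUROC could be selection optimism:
the best of 9,948 models is reported. The null rebuilds that optimism:
each replicate assigns 7 lesions to the melanoma class uniformly at random
(lesion-level, ignoring patient structure; draws are made over the sorted
lesion ordering so results do not depend on dataset row order), reruns the
full subset search on the cached fold projections, and records the maximum
AUROC. The summary is the exceedance fraction P(best AUROC > cutoff), with
strict inequality at the default cutoff 0.9. Replicates are derived from one
seed and reproducible bit for bit.

Each replicate's search dominates the cost, so desk-scale runs cap the
per-replicate search space (`analysis/05_randomize.R` uses 99 replicates
over the 120 subsets of size ≤ 2 from the first 15 PCs, a few minutes on one
CPU); the cap is a parameter, not a constant. Under LOLOCV with an
intercept-sensitive model the null distribution sits well *below* 0.5 on
average (holding out a positive lesion depresses its posterior), so low null
AUROCs are expected, not a bug.

## Problem sizes used by the tests

Unit tests run on reduced cohorts (8–14 lesions) and shorter grids chosen to
keep the grid spacing comparable to the default 0.5 cm⁻¹ relative to band
widths wherever preprocessing quality is asserted; coarser grids make peaks
artificially sharp under fixed smoothing/median windows. The end-to-end
recovery checks use the full default cohort (60 lesions, 1980-point grid,
all 9,948 subsets) and a 20-replicate null on a reduced subset space; the
whole suite completes in a few minutes on one CPU.

## File formats

Cohorts are exchanged as two UTF-8 comma-separated files: a wide spectra
table (header `measurement_id` then the wavenumber grid; one row per
measurement) and a manifest (`measurement_id`, `lesion_id`, `patient_id`,
`label`, optional `stage`). All numbers are written at full decimal
precision (`%.17g`) so a write/read cycle reproduces intensities and grids
to better than 1e-12 — headers rounded for display would silently break
round-trip identity on irrational grid steps. Binary spectroscopy formats
(SPC, JCAMP-DX) and cross-grid resampling are out of scope.

## Limitations

* All performance statements are about synthetic cohorts; nothing here
  validates clinical accuracy.
* The specific best PC subset is cohort-dependent and not meaningful across
  cohorts (on the default synthetic cohort many subsets tie at AUROC 1).
* Broad-band constituents are partially absorbed by polynomial baseline
  removal (see above).
* The bootstrap band and the randomization null both resample lesions,
  ignoring the mild patient-level structure.
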