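---
title: "Methods: the radscore phantom-to-score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the radscore phantom-to-score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`radscore` studies how a CT radiomics classification pipeline behaves —
feature reliability under reader variation, penalized feature selection,
train/test generalization — for the problem of separating upper-tract
urothelial carcinoma (UTUC) of the renal pelvis from renal cell
carcinoma (RCC) on venous-phase CT. Because no patient imaging is
distributed with the package, the first stage is a synthetic tumor
phantom generator whose cohort-level structure is calibrated to the
published characteristics of a 236-patient cohort. This vignette
documents the models, the parameters that matter, the numerical
conventions, and what conclusions the synthetic setting does and does
not support.

## The phantom generator

Each lesion is an axis-aligned ellipsoid voxelized on a regular grid
(default spacing 1 × 1 × 3 mm, mimicking soft-kernel axial CT
reconstructed at 3 mm; grids are sized per lesion with a 4 mm margin).
Per class, four ingredients are drawn or fixed:

* **Size.** The long axis is log-normal:
  `L ~ exp(N(log(size_median_mm), size_log_sd^2))`. Log-normality gives
  positive support and right skew, which matches how tumor size
  distributions with a low median but occasional large masses behave.
  Defaults: UTUC median 42 mm with `size_log_sd = 0.514`, RCC median
  81 mm with `size_log_sd = 0.397`; the log-SDs are back-computed from
  the published interquartile ranges (2.9–5.8 cm and 5.8–9.9 cm) via
  `log(q3/q1) / (2 × 0.6745)`. The short axes are `L` times a ratio
  drawn uniformly from `axis_ratio_range` (default 0.5–0.85).
* **Attenuation and texture.** In-mask voxels are
  `mean_hu + noise`, where the noise is white Gaussian noise smoothed
  with a Gaussian kernel of width `texture_corr_mm` (a Gaussian random
  field, implemented by FFT convolution on the periodic grid) and
  rescaled to `noise_sd_hu`. This is the minimal texture model with a
  single controllable correlation length; real enhancement patterns are
  not modeled. Subtype defaults place clear cell RCC highest
  (95 HU, strong heterogeneity), papillary RCC lowest among RCC
  (45 HU), and UTUC at 42–50 HU — the qualitative venous-phase ordering
  of these entities — so that each classification task is learnable but
  not trivial.
* **Necrosis.** With probability `necrosis_prob` a concentric core at
  half the lesion's linear scale receives `necrosis_hu_offset`
  (default −40 HU), giving a hypodense center.
* **Background.** A homogeneous −50 HU slab. Only in-mask voxels enter
  feature extraction, and a test asserts that out-of-mask values are
  irrelevant, so the background is cosmetic.

The default cohort reproduces the published composition exactly:
236 cases — 87 clear cell, 20 papillary, 5 chromophobe, 3 sarcomatoid
and 4 other RCC (119), 85 high-grade and 32 low-grade UTUC (117). A
randomly chosen `ceiling(0.30 × n)` of cases carries a second-reader
mask. Everything is a pure function of the configuration, including its
seed; per-case seeds are drawn once from the master seed.

**Size metric.** The published "median tumor size" does not state
whether it is a long axis or an equivalent diameter; the generator
calibrates the *long axis* to the printed medians and records both axes
and the ellipsoid volume per case, so either convention can be
inspected.

**Second reader.** The published protocol says only that a second
radiologist adjusted segmentations at their discretion. We model this
as a boundary-localized stochastic deformation: the binary mask is
smoothed with a Gaussian of width `jitter_mm`, a correlated noise field
of relative amplitude 0.2 is added, and the 0.5 level set is
re-thresholded. Voxels with smoothed value above 0.99 / below 0.01 are
never flipped, which confines changes to a boundary shell of a few
`jitter_mm` and guarantees the lesion interior survives. `jitter_mm = 0`
is the identity; mean Dice overlap with the original decreases
monotonically in `jitter_mm` (tested by Monte Carlo). The default
1.5 mm produces high but imperfect feature reliability at the default
tumor sizes, which is the regime an ICC screen is for.

## The 59-feature panel

The exact published feature roster lives in vendor software and an
unavailable supplement, so the package registers its own versioned
roster (`panel-59-v1`) constrained to contain every feature named in
the published coefficient tables: 16 histogram-domain first-order
features (computed on discretized gray levels), 19 intensity-domain
first-order features (raw HU), 22 GLCM features, and the long/short
ellipsoid axes. No numeric equivalence to the vendor implementation is
claimed.

Numerical conventions, chosen once and tested against independent
brute-force oracles:

* **Discretization**: fixed bin number (default 32) over the in-mask
  `[min, max]`; the maximum maps to the top bin; a constant lesion maps
  to bin 1. Fixed-bin-number is the scanner-robust standard when no
  calibrated bin width is published.
* **Entropy** is Shannon entropy in bits (log₂) over occupied bins;
  moments use population (divide-by-n) conventions; percentiles use R's
  default quantile type 7. The robust mean absolute deviation averages
  `|x − mean(trimmed)|` over values inside the closed [P10, P90]
  interval.
* **GLCM**: distance 1 voxel, all 13 unique 3D directions, symmetric
  pairs (both orders counted), per-direction normalization then
  averaging over directions that contain at least one pair; a pooled
  "merge" policy is available. Offsets are in voxel units regardless of
  anisotropic spacing, matching common practice. A single-voxel region
  has no pairs: the GLCM is flagged degenerate and all 22 features are
  0 rather than NaN. GLCM correlation of a zero-variance (point-mass)
  matrix is defined as 1.
* **Axes**: PCA of the physical coordinates of in-mask voxels; the full
  axis is `2√(5λ)` per eigenvalue λ — the axis of the uniform solid
  ellipsoid with that second moment (variance a²/5 along a semi-axis
  a). This recovers the analytic axes of digital ellipsoids to within
  discretization error (~2–5%), which some popular `4√λ` conventions do
  not.

## Reliability screening

Interreader agreement per feature is ICC(2,1) — two-way random
effects, absolute agreement, single rater:

    ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)),  k = 2.

The published text says only "ICC"; ICC(2,1) is the standard choice in
radiomics reliability work because it penalizes systematic reader
offsets. Features with ICC ≥ 0.8 are retained, in panel order. The two
size features pass through the same screen as everything else (the
published phrasing would also support exempting them; screening
everything is the stricter default, and the axes are extremely reliable
under boundary jitter anyway). Exactly identical readings are retained
with ICC 1 by construction; features whose pooled values are constant
to within 1e−12 are dropped with an explicit report entry rather than
returning 0/0.

## The radiomic score

Retained features are z-scored with means/SDs estimated on the
training split only (zero-variance features are excluded with a
report); test data always use training parameters. The score model is
L1-penalized logistic regression (glmnet, `α = 1`, unpenalized
intercept, no internal standardization since inputs are already
z-scored). The penalty grid is glmnet's: 100 log-spaced values from the
smallest all-zero penalty down to 1e−4 of it. λ is chosen as
`lambda.min` under 10-fold stratified, seeded cross-validation.

The published description is ambiguous — "tuned for maximum accuracy"
vs "minimum mean cross-validated error". Binomial deviance (the glmnet
default error) is our default; misclassification error is selectable
via `cv_metric = "class"`. Neither is asserted to be what the original
analysis used.

The score of a case is `plogis(β₀ + βᵀ z(x))`. ROC analysis computes
the AUC as the normalized Mann–Whitney U statistic with midrank tie
handling (identical to trapezoidal integration of the empirical curve),
and the operating cutoff maximizes the Youden index, ties broken toward
the lower cutoff. The published reports give distinct cutoffs for
training and validation cohorts without naming the rule; Youden is the
standard that reproduces that pattern, so the experiment report carries
both the train-derived cutoff applied to the test split and a
test-optimized cutoff, explicitly labelled.

## The experiment pipeline

`run_experiment()` executes: phantoms (or supplied cases) → extraction
for both readers → ICC screen → task selection → stratified split →
z-score fit on train → cross-validated LASSO → ROC on train and test.

* **Split.** `round(fraction × n)` training cases, allocated across
  classes by largest remainder; 236 cases at 0.70 give 165/71 with
  82 UTUC + 83 RCC in training. Stratification is a package choice (the
  original text says only "randomly divided"); it stabilizes small
  subcohorts.
* **Tasks.** Four label mappings: all cases; clear cell RCC vs
  high-grade UTUC (87 + 85 = 172 under the default mix); high- vs
  low-grade UTUC (117); UTUC vs non-clear-cell RCC. The last keeps all
  UTUC plus papillary/chromophobe/sarcomatoid/other RCC, i.e.
  117 + 32 = 149 under the default mix; the published n = 144 for this
  subgroup is not decomposable from the published subtype table, so the
  package documents its own composition and asserts nothing about 144.
* **Leakage.** By default the ICC screen uses the full dual-read
  subsample before splitting, mirroring the published ordering of
  methods (reliability filtering is described before model building).
  That subsample can contain future test cases, which is a mild,
  documented leak of *mask-agreement* information (not labels). The
  strict mode `icc_scope = "train"` restricts the screen to dual-read
  training cases; in that mode a test verifies bit-identity of every
  train-derived artifact (normalization, retained set, λ, coefficients,
  train cutoff) when test-split volumes are arbitrarily corrupted.

## What the tests do and do not show

Property tests run on scaled-down phantoms (14–20 mm tumors at 1 mm
isotropic spacing, cohorts of 40–400) so the full suite runs in about a
minute; the study-calibrated defaults are exercised through the
geometry fast path (`generate_cohort(..., voxelize = FALSE)` and
`sample_geometry()`), which reuses the voxelizer's own draw stream.
Key verified properties: every feature equals an independently coded
brute-force oracle on random small ROIs; ICC matches a two-way ANOVA
computed by `lm`/`anova`; AUC matches explicit pair counting and an
established ROC implementation; the LASSO reproduces the unpenalized
`glm` fit at λ = 0 and the `logit(prevalence)` intercept at full
shrinkage, with monotone sparsity along the path; phantom cohorts with
identical class parameters give chance-level held-out AUC while a 3-SD
attenuation gap gives AUC ≥ 0.95; and train AUC exceeds test AUC on
average over replicates.

Passing all of this shows the *statistical machinery* is correct and
leak-free. It does not validate clinical discrimination of UTUC vs RCC:
phantoms are ellipsoids with stationary Gaussian texture, single-phase,
with no scanner, reconstruction-kernel, contrast-timing or
inter-institutional variability, no irregular margins, no infiltration
of the collecting system — precisely the features a real radiomic model
may be exploiting. The published patient-level AUCs and coefficients
are therefore used only as report-format references, never as targets.

## Known limitations

* Ellipsoidal geometry makes shape oracles analytic but under-disperses
  shape features; irregular lesions would widen their ICC and
  coefficient distributions.
* GLCM offsets ignore anisotropic spacing (voxel-unit convention);
  enabling isotropic resampling before extraction is left off by
  default to match thick-slice practice.
* The 59-feature roster is a registered stand-in for an undisclosed
  vendor panel; absolute feature values are not comparable to vendor
  output.
* Wavelet/filtered features and run-length/size-zone families are out
  of scope (the modeled panel is first-order + GLCM + size only).
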