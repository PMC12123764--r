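# radscore

Radiomic scores for separating upper-tract urothelial carcinoma (UTUC)
from renal cell carcinoma (RCC) on venous-phase CT.

Distinguishing UTUC of the renal pelvis from RCC before surgery matters
because the two entities are operated differently (radical
nephroureterectomy with bladder-cuff excision vs partial/radical
nephrectomy), yet imaging appearances overlap for locally advanced
masses and biopsy is invasive and error-prone. `radscore` implements a
complete, reproducible radiomics pipeline for this problem, aimed at
methodologists who want to study the behavior of such pipelines without
access to patient imaging:

1. **Synthetic tumor phantoms** — a seeded generator of 3D lesions
   (ellipsoidal masks in HU volumes) with class-conditional size,
   attenuation, texture-correlation and necrosis structure, emulating a
   236-case cohort (117 UTUC / 119 RCC with the published subtype mix,
   class median long axes 4.2 cm / 8.1 cm) and a 30% dual-read
   subsample with a perturbed second-reader mask.
2. **Feature extraction** — a versioned 59-feature panel per lesion:
   16 histogram-domain and 19 intensity-domain first-order statistics,
   22 gray-level co-occurrence matrix (GLCM) texture features
   (distance 1, 13 directions, symmetric pairs, per-direction
   normalization then averaging), and the two ellipsoid-equivalent tumor
   axes from PCA of the mask coordinates.
3. **Reliability screening** — per-feature interreader agreement via the
   two-way random-effects, absolute-agreement, single-rater intraclass
   correlation ICC(2,1); features with ICC ≥ 0.8 are retained.
4. **Radiomic score** — features are z-scored with training-split
   parameters and fed to an L1-penalized logistic model
   (`glmnet`, α = 1): minimize the mean negative binomial log-likelihood
   plus λ·Σ|βⱼ|, with λ chosen as `lambda.min` by 10-fold stratified
   cross-validation. The score of a lesion is the fitted probability
   σ(β₀ + βᵀz(x)) ∈ [0, 1].
5. **Evaluation** — ROC analysis (AUC = normalized Mann–Whitney U) with
   a Youden-index operating cutoff (J = sensitivity + specificity − 1),
   on a stratified 70/30 train/test split, for four tasks: UTUC vs RCC,
   ccRCC vs high-grade UTUC, high- vs low-grade UTUC, and UTUC vs
   non-clear-cell RCC.

The central fitter `fit_radiomic_score()` returns a classed S3 model
with `print`, `summary`, `coef`, `predict` and `plot` methods;
`run_experiment()` wires all stages together with strict
train/test-separation guarantees.

## Worked example

```r
library(radscore)

cfg <- experiment_config(default_cohort_config(n_cases = 80, seed = 42),
                         task = "UTUC_vs_RCC", folds = 5, seed = 42)
ex <- run_experiment(cfg)
ex
#> Radiomics experiment: UTUC_vs_RCC
#>   cohort: RCC = 40, UTUC = 40 (train 56 / test 24)
#>   ICC-retained features: 16 of 59
#>   selected by LASSO: 5 features
#>   train: AUC 0.982, cutoff 0.615 (sens 0.929, spec 0.964)
#>   test:  AUC 0.917; at train cutoff: sens 0.833, spec 0.917
#>          test-optimized cutoff 0.321 (sens 1.000, spec 0.917)
```

Reading this: 80 phantoms were generated with the study-calibrated
class structure; 16 of 59 features survived the ICC ≥ 0.8 interreader
screen on the dual-read subsample; the cross-validated LASSO kept 5 of
them. The radiomic score separates the classes with a train AUC of
0.982 and a held-out AUC of 0.917; at the train-derived Youden cutoff
of 0.615, test-set sensitivity/specificity are 0.833/0.917. The largest
coefficients sit on an intensity percentile and the tumor long axis —
the phantom classes differ most in attenuation and size, so this is the
expected physics of the generator, not a clinical claim.

Individual stages are available directly:

```r
p  <- phantom_class_params("UTUC", size_median_mm = 42, size_log_sd = 0.51)
tv <- generate_tumor_volume(p, spacing_mm = c(1, 1, 3), seed = 1)
v  <- extract_panel(volume = tv$volume, mask = tv$mask)   # 59 features
m2 <- perturb_mask(tv$mask, jitter_mm = 1.5, seed = 2)    # second reader
icc_two_readers(rnorm(10), rnorm(10))                     # ICC(2,1)
```

## Limitations

Phantoms are ellipsoidal, single-phase, and texture is a smoothed
Gaussian random field — they validate the pipeline's statistical
machinery, not the clinical performance of any scanner protocol. See
the methods vignette (`vignettes/radiomic-score-pipeline.Rmd`) for the
full model description, parameter choices and known limitations.
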