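Package: radscore
Title: Radiomic Scores for Differentiating Upper-Tract Urothelial and Renal
    Cell Carcinoma on CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end CT radiomics pipeline for separating upper-tract
    urothelial carcinoma (UTUC) from renal cell carcinoma (RCC) on
    venous-phase imaging. Provides a synthetic 3D tumor-phantom cohort
    generator with class-conditional size and texture structure, NIfTI
    volume/mask input-output, a 59-feature radiomic panel (first-order
    histogram and intensity statistics, gray-level co-occurrence matrix
    texture features, and ellipsoid-equivalent tumor axes), interreader
    reliability screening by intraclass correlation ICC(2,1), a
    cross-validated L1-penalized logistic radiomic score fitted with glmnet
    on z-scored features, and ROC analysis with Youden-index operating
    cutoffs. The central fitter returns a classed model object with the
    usual print, summary, coef, predict and plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
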