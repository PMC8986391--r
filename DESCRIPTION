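Package: hdpscreen
Title: First-Trimester Screening Risk Models for Hypertensive Disorders of
    Pregnancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for first-trimester prenatal screening of hypertensive
    disorders of pregnancy (HDP) from a four-marker panel: maternal serum
    D-dimer, PAPP-A, free beta-hCG and fetal nuchal translucency.
    Implements multiple-of-median (MoM) normalization with gestational-age
    median regression and maternal-weight correction, per-group multivariate
    Gaussian likelihood-ratio risk models over ten marker combinations with
    a maternal-age prior, and the full screening evaluation battery (ROC
    curves with DeLong confidence intervals, Youden-index cut-offs,
    sensitivity, specificity, predictive values and diagnostic likelihood
    ratios).  A synthetic cohort generator reproduces the group-wise marker
    and demographic distributions of a published case-control study so the
    whole pipeline can be exercised and tested without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
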