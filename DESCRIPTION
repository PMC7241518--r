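Package: probuse
Title: Claims-Based Phenotyping of Problem Prescription Opioid Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Develops and evaluates computable phenotyping algorithms for
    problem prescription opioid use among long-term extended-release/long-acting
    (ER/LA) opioid recipients, from structured EHR/claims-style tables. Provides
    a seeded synthetic claims simulator (Sentinel-CDM-like demographics,
    enrollment, encounters, diagnoses, procedures and dispensings with a latent
    problem-use process), cohort eligibility and index-date determination,
    stratified sampling with inverse-probability design weights, a library of
    dispensing/diagnosis/encounter predictor builders (morphine-equivalent dose
    series, overlapping-fill detection, concomitant-use measures), adaptive
    LASSO logistic regression with ridge-derived penalty weights selected by
    cross-validated grid search, and cut-point-based evaluation against a
    reference standard (sensitivity, specificity, PPV, NPV, ROC, and an ICD-9
    code comparator).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
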