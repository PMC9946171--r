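Package: edscores
Title: Validation of Early Warning Scores for 24-Hour Mortality in Emergency Department Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate bedside risk scores for death within 24 hours of
    emergency department (ED) arrival. Computes the National Early Warning Score
    (NEWS) and the respiratory rate and oxygenation (ROX) index from first-recorded
    vital signs, handles missing vitals by multiple imputation with chained
    equations (predictive mean matching), and assesses the scores by discrimination
    (ROC AUC with DeLong confidence intervals and paired DeLong comparison),
    calibration against observed mortality per score value, and decision curve
    analysis with standardized net benefit. Includes a synthetic ED cohort
    generator with a latent-severity model, configurable missingness mechanisms
    (MCAR, MAR, MNAR), and an end-to-end study pipeline with split-sample and
    sensitivity analyses, so the full evaluation is reproducible without access
    to restricted patient registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    jsonlite,
    yaml,
    readr,
    withr,
    MASS,
    splines
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
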