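Package: prenatalrisk
Title: Exact Logistic Regression and Risk-Score Derivation for
    Sparse-Event Perinatal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving and evaluating integer clinical risk
    scores from sparse-event cohort data, built around exact conditional
    logistic regression. Enumerates the exact conditional distribution of
    each parameter's sufficient statistic from grouped binary data,
    computes conditional maximum likelihood and median unbiased odds-ratio
    estimates with exact equal-tail confidence intervals and exact
    p-values, discretizes adjusted odds ratios into integer score weights,
    and evaluates scores with classification tables, AUC with DeLong
    confidence intervals, and Youden-based cut-off selection. Includes a
    synthetic-cohort generator emulating Japanese pregnancy-notification
    questionnaire data with municipality-dependent item availability, and
    an end-to-end pipeline from raw records to a scored, evaluated cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
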