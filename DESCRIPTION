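Package: clifr
Title: Common Longitudinal ICU Data Format Tools for Federated Critical Care Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the Common Longitudinal ICU data Format
    (CLIF), a relational table format for critical-care electronic health
    record data. Provides the table schema registry and controlled-vocabulary
    (mCIDE) validation engine, a synthetic multi-site ICU encounter generator
    with known ground truth, ICU cohort discovery with consortium-style
    outlier handling, first-24-hour feature extraction with a gradient-boosted
    mortality model harness, 72-hour temperature-trajectory subphenotype
    classification by minimum mean squared error with covariate-adjusted
    outcome models, a prognostic-model evaluation suite (AUC with DeLong
    confidence intervals, Brier score, calibration curves, decision-curve
    analysis), and federated aggregation of per-site summaries into
    consortium-level tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    arrow,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
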