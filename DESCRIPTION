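Package: screenaudit
Title: Auditing Race and Ethnicity in Advanced Breast Cancer Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing algorithmic bias in screening-based advanced
    breast cancer risk prediction. Fits per-screening-round logistic models
    for advanced cancer and competing events, stratified by menopausal status
    and screening interval, in two variants (including and excluding race and
    ethnicity), compounds them into cumulative 6-year risks under competing
    risks, and quantifies how removing race shifts calibration
    (expected/observed ratios), discrimination (cross-validated AUC), and
    percentile-based risk-category assignment across race and ethnicity
    groups. Includes a synthetic screening-cohort generator with configurable
    covariate structure, rare-outcome rates, and missingness, plus multiple
    imputation by chained equations and direct standardization to a reference
    population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
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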