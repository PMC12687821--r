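Package: nocturne
Title: Personalized Next-Day Headache Forecasting from Nocturnal Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forecasting next-day migraine and headache from
    nocturnal autonomic and sleep data recorded by wrist-worn wearables.
    Includes a synthetic cohort simulator with plantable pre-headache
    autonomic signatures, readers and writers for minute-level record and
    headache-diary tables, out-of-bed exclusion and chained-equations
    imputation, 5-minute interval feature extraction, group-level linear
    mixed-effects comparisons, a per-participant nested leave-one-night-out /
    leave-two-nights-out cross-validation framework over elastic-net,
    random-forest and gradient-boosting learners with interval-to-night
    probability aggregation, threshold and curve-based evaluation metrics,
    SHAP feature attribution, and generalized additive model smooths of
    nocturnal signal dynamics.
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
    glmnet,
    jsonlite,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
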