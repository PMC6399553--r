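Package: preopssi
Title: Preoperative Surgical Site Infection Risk Modelling from Temporal Blood-Test Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting surgical site infection (SSI) from
    preoperative laboratory time series. Irregular blood-test measurements are
    aggregated to a daily grid, imputed (last observation carried forward,
    k-nearest neighbours, or a hybrid of the two), and abstracted into
    short/medium/long temporal-window features (means, trends, testing counts
    and proportions, abnormal-value flags). Models are L1-penalized logistic
    regressions with per-feature penalty factors derived from blood-test
    prices and an early-stopping cap on the number of selected features.
    Includes a repeated-holdout evaluation harness with cost accounting, an
    exhaustive window-partition optimizer, and a seeded synthetic cohort
    generator emulating the statistical structure of preoperative EHR data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
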