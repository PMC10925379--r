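Package: uqcascade
Title: Uncertainty-Gated Multi-Stage Classification with Ensemble
    Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-stage cascade classifier for settings where part of
    the feature set is expensive to acquire (e.g. SPECT myocardial perfusion
    imaging on top of routine clinical and ECG variables). A first-stage
    ensemble of pseudo-bootstrapped elastic-net logistic models predicts the
    outcome with quantified uncertainty from cheap features; a rule-based
    gate escalates only uncertain patients to a second-stage ensemble that
    additionally uses the expensive features. Gate thresholds are tuned by a
    scaled-weighted-AUC objective inside a nested cross-validation protocol
    with two held-out validation slices. Includes DeLong and McNemar model
    comparisons, permutation feature importance, a guideline rule-table
    comparator, and a synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
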