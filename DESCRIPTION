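Package: gaitdss
Title: Decision Support from Clinical Gait Analysis Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build a probabilistic clinical decision support system
    from three-dimensional gait analysis data in children with cerebral palsy.
    Extracts 49 rule-based binary features from lower-limb joint-angle curves
    time-normalized to 101 points of the gait cycle, using reference bands
    (mean and SD of curve statistics) computed from typically developing
    children. Combines the features with physical-examination predictors to
    train per-outcome classifiers (random forest, stratified balanced random
    forest, elastic-net logistic regression) under 25 out-of-bag bootstrap
    resamples, scored and tuned by the weighted Brier score, with isotonic
    probability calibration, variable-importance explanations and partial
    dependence. Includes a synthetic-data generator (reference cohorts,
    feature implantation, clinical cohorts with known logistic structure) so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
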