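Package: frailtrans
Title: Frailty Transition Classification and Gender-Stratified Prognostic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transitions between frailty phenotype states
    (robust, prefrail, frail, death) in older community-dwelling cohorts.
    Scores the five-item frailty phenotype with a conservative missing-item
    rule, classifies death-inclusive transition outcomes, derives standard
    dichotomised clinical predictors, and develops gender-stratified prognostic
    logistic models via multiple imputation by chained equations,
    bootstrap-stability backward-AIC variable selection, Rubin's-rules pooling,
    and bootstrap internal validation (optimism-corrected c-index and
    bias-corrected calibration). Includes a calibrated synthetic cohort
    generator so the full pipeline can be exercised and tested end to end
    without access to individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nnet,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
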