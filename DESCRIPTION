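Package: invasdm
Title: Presence-Only Ensemble Species Distribution Modelling with
    Effort-Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for presence-background species
    distribution modelling of range-expanding species across a native and
    an invasive region. Builds a community-science sampling-effort layer,
    thins and filters occurrence records under region-specific positional
    uncertainty thresholds, draws replicated pseudo-absence sets with
    cell- or uncertainty-buffer exclusion, fits a multi-algorithm
    classifier registry over repeated stratified splits, combines members
    into mean, committee-average and skill-weighted ensembles, evaluates
    them with the True Skill Statistic and the continuous Boyce index
    stratified by region, quantifies predictor influence by permutation
    importance, contrasts regions with a beta-regression mixed model, and
    projects suitability maps with standardized effort. A synthetic
    landscape generator provides effort-biased occurrence samples with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    rpart,
    nnet,
    xgboost,
    glmmTMB,
    emmeans,
    jsonlite,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
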