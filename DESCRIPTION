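Package: hexinvade
Title: Hexagon-Grid Invasion-Risk Modelling for Forest Pests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the spread of invasive forest insects such as
    the emerald ash borer on a hexagonal landscape tessellation. Builds
    equal-area hexagon grids, computes a lagged negative-exponential
    infestation-pressure ("force of invasion") predictor from neighbourhood
    infestations, fits and compares driver-grouped logistic regression models
    by AIC with collinearity screening and backward elimination, runs a
    six-algorithm species-distribution-model comparison (GLM, MARS, ANN, CTA,
    GBM, RF) with balanced pseudo-absence sets scored by the True Skill
    Statistic, builds committee-averaging ensembles, computes permutation
    variable importance and marginal response curves, and projects risk to
    uninvaded regions. Includes a stratified-dispersal invasion simulator with
    known parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    rpart,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
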