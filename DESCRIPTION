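Package: phimap
Title: Metabolic Index Calibration and Aerobic Habitat Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates the metabolic index (the ratio of ambient oxygen supply
    to temperature- and mass-dependent resting oxygen demand) for marine
    ectotherms from intermittent-flow respirometry trials, including standard
    and maximum metabolic rate estimation, critical oxygen level (O2crit)
    regression, mass scaling and piecewise Arrhenius fitting. Projects the
    calibrated index over gridded ocean temperature and oxygen layers, builds
    random-forest presence/pseudo-absence distribution ensembles, and extracts
    the critical index threshold limiting a species' range via a tree-path
    feature-contribution decomposition and logistic regression. Ships a
    planted-truth synthetic data generator (respirometry cohorts, seasonal
    ocean grids, occurrence sets) so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
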