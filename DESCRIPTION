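Package: BarkBeetleNet
Title: Deep Convolutional Prediction of Bark Beetle Infestation Risk on
    Landscape Rasters
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts annual bark beetle (Ips typographus) infestation risk
    for 30 m grid cells from the local host-tree and recent-attack
    neighborhood, long-term mean annual temperature, and the regional
    outbreak stage. Implements the full pipeline: raster ingestion and
    validation, moving-window example encoding (19 x 19 neighborhoods, 363
    input variables), outbreak-stage classification by terciles of regional
    disturbed timber, a hybrid convolutional neural network with a linear
    baseline, F1-maximizing threshold calibration, an evaluation suite for
    imbalanced binary maps (accuracy, precision, recall, F1, Conditional
    Kappa, True Skill Statistic, Gleichlaeufigkeit), year-holdout and
    random-split experiment designs, and a contagious outbreak-landscape
    simulator for fully reproducible testing without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
VignetteBuilder: knitr
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'BarkBeetleNet-package.R'
    'dataset.R'
    'metrics.R'
    'nnet-engine.R'
    'model.R'
    'experiments.R'
    'landscape-io.R'
    'simulate.R'
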