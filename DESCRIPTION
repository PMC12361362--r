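Package: cardiodetect
Title: Heart Disease Detection and Atrial Fibrillation Rate Estimation with
    Ship-Rescue Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tabular clinical-data pipeline for early heart-disease
    screening. An enhanced adaptive-velocity ship-rescue optimizer (EAVSRO)
    drives three stages: chi-square-scored weighted feature selection, a
    hybrid deep-feature extractor with an RBF-kernel support-vector-machine
    decision head for binary disease detection, and a multi-scale
    convolutional capsule network with dynamic routing for continuous
    atrial-fibrillation (AF) rate regression. Includes the full suite of
    confusion-matrix and regression error metrics used to score the stages
    (CSI, FPR, MCC, F1, SMAPE, MAE, MPE, RMSE), a synthetic clinical-data
    generator with planted informative features and a known AF-rate
    generative function, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
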