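Package: spvs
Title: Sensor-Failure-Tolerant Ensemble Classification for Electronic-Nose Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ensemble classification of multichannel gas-sensor (electronic
    nose) data that remains operational when individual sensors fail. One base
    classifier (k-nearest neighbours, CART decision tree, or linear
    discriminant analysis) is trained per sensor channel and test samples are
    labelled by plurality voting over the classifiers of the sensors that are
    still available; failed channels are simply excluded from the vote rather
    than imputed. Includes readers/writers for delimited sensor tables,
    min-max and z-score normalisation, seeded sensor-failure simulation
    protocols, stratified k-fold cross-validated evaluation (accuracy,
    macro-averaged sensitivity and specificity), and a seeded generator of
    synthetic e-nose spoilage datasets for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    rpart,
    class
Config/testthat/edition: 3
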