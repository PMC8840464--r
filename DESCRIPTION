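Package: sonoselect
Title: Metaheuristic Deep-Feature Selection and Probability Fusion for
    Breast Ultrasound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for lesion classification from
    grayscale breast ultrasound images: exact-permutation augmentation
    with class balancing, a pluggable deep-feature extraction contract
    with a deterministic multiscale mock extractor, two wrapper feature
    selectors (a reformed differential evolution with a standard-error
    threshold and a reformed binary grey-wolf optimizer with a sigmoid
    transfer and stochastic crossover), probability-based serial fusion
    of the selected feature sets, and a multiclass evaluation layer with
    macro metrics and Nemenyi critical-difference ranking. Includes
    synthetic image and feature-matrix generators with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    class,
    e1071,
    MASS,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
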