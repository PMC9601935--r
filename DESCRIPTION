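Package: gamlp
Title: Genetic-Algorithm Optimisation of Multilayer Perceptrons for
    Cervical Cancer Risk-Factor Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated tabular-classification pipeline for cervical
    cancer screening data in the layout of the UCI "Cervical Cancer
    (Risk Factors)" table. A genetic algorithm evolves multilayer
    perceptron hyperparameter chromosomes (activation function, solver,
    and two hidden-layer sizes); the fitness of each chromosome is the
    cross-validated classification accuracy of the trained network.
    Around this core the package provides preprocessing (factor drops,
    missing-row filtering, min-max normalization), class balancing by
    random oversampling, four feature-selection modes (two-component
    PCA, all factors, and random-forest importance top-18/top-10),
    confusion-matrix metrics, a stratified k-fold evaluation harness
    with configurable leakage placement, a registry of baseline
    classifiers, a 16-scenario/160-experiment grid runner, a synthetic
    data generator with planted factor-label signal, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
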