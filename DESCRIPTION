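Package: slicfuse
Title: Superpixel-Guided Feature Fusion and Wrapper Selection for
    Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks for a two-class histopathology image
    classification pipeline: entropy-guided SLIC superpixel segmentation
    with Kapur maximum-entropy multilevel thresholding and piecewise
    power-law contrast enhancement, deep-weighted averaging feature fusion
    (DWAFF) of multi-backbone feature matrices, particle swarm and red
    deer metaheuristic wrapper feature selection, formula-level
    classifiers (softmax discriminant, Bayesian linear discriminant,
    multilayer perceptron) alongside delegated baselines, a stratified
    K-fold evaluation harness with the full confusion-matrix metric
    suite, and synthetic image/feature generators so every stage is
    testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    ranger,
    rpart,
    png,
    tiff,
    jsonlite
Suggests:
    EBImage,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
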