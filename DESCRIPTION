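Package: stec
Title: Spatio-Temporally Efficient Coding in Hierarchical Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains small bidirectional hierarchical networks of sigmoid
    units on moving patches of procedurally generated natural-scene
    surrogates under a combined temporal-smoothness and response-entropy
    objective (spatio-temporally efficient coding), and quantifies the
    robustness of the learned representations of moving bar stimuli via
    correlation structure, static-versus-moving response distances, and
    cross-condition population decoding. Includes the spatial-only and
    temporal-only limiting regimes as controls, a full bar-stimulus and
    gaze-sequence generator, noise augmentation for decoder training, six
    decoder families, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
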