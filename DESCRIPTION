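Package: hmaxtp
Title: Temporal Pooling in a Hierarchical Model of Object Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A four-stage HMAX-style feedforward model of the ventral visual
    stream (Gabor simple cells, local max pooling, Gaussian-tuned shape
    templates imprinted from image patches, global max pooling), extended
    with an unsupervised temporal-pooling mechanism that groups multiple
    views of a feature sampled within a short window of an object
    transformation sequence into one feature column.  Includes parametric
    generators for geon-style stimulus families (a base shape, graded
    metric variants, and a pixel-calibrated non-accidental variant) and for
    synthetic video sequences of objects undergoing combined translation,
    scaling and in-depth rotation, plus an evaluation suite measuring
    percent modulation of model units for non-accidental versus metric
    shape changes and viewpoint-generalization accuracy of a linear
    support-vector classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    e1071,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
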