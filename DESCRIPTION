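Package: longfission
Title: Classification of Longitudinally Dividing Bacteria from
    Phase-Contrast Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting longitudinal bacterial
    fission in phase-contrast microscopy images. Generates synthetic
    microscope images of rod-shaped cells with known morphology and
    ground-truth bounding boxes; extracts single-cell crops by Otsu
    binarization, connected-component labeling and bounding boxes;
    partitions crops into stratified train/validation/test splits; trains
    a width-scalable ResNet-18 binary classifier (implemented from first
    principles, with minibatch stochastic gradient descent, momentum,
    step learning-rate decay and optional transfer learning from a
    self-pretrained checkpoint); and evaluates with confusion matrices,
    precision, recall and F1. Includes a compensated (Kahan) accumulator
    for numerically stable metric averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
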