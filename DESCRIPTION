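Package: hardvessel
Title: Harmonic Densely Connected Networks for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise segmentation of blood vessels in color fundus
    photographs with a harmonic densely connected encoder, receptive-field-block
    skip modules and a cascaded partial decoder with multiplicative dense
    aggregation, trained under an edge-weighted IoU + binary cross-entropy loss.
    Includes a synthetic fundus simulator producing paired vessel and
    field-of-view ground truth, DRIVE/CHASE-style dataset I/O with pad-and-crop
    geometric normalization and randomized augmentation, a compact CPU compute
    engine (reverse-mode differentiation over im2col/GEMM convolutions), an Adam
    training loop with a staged learning-rate schedule, and FOV-restricted
    evaluation (sensitivity, specificity, F1, accuracy, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
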