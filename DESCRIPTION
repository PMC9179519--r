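Package: dualrad
Title: Dual-Purpose Autoencoder Segmentation and Radiomics for Breast
    Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A computer-aided diagnosis pipeline for breast ultrasound
    imaging built around a convolutional autoencoder that segments
    lesions while emitting a low-dimensional latent radiomic vector from
    its bottleneck.  The package also extracts a 354-feature conventional
    radiomic panel (first-order, shape, and gray-level texture matrices
    on the original image plus Laplacian-of-Gaussian and stationary
    wavelet derived images), reduces it to a compact spectral embedding
    via Laplacian eigenmaps, and classifies benign versus malignant
    lesions with a random forest under leave-one-out cross-validation.
    A seed-deterministic speckle phantom generator provides synthetic
    cohorts so the full pipeline is testable end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    randomForest,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
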