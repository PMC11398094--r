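Package: fibermap
Title: Distance-Map Regression for Fiber Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates fiber diameters from digital micrographs by regressing
    Euclidean distance maps with convolutional encoder-decoder networks. The
    package simulates realistic fiber micrographs (mu-randomness carrier lines
    with sinusoidal curvature, per-fiber grayscale and Gaussian noise),
    computes exact Euclidean distance-transform labels, trains U-Net style
    regressors (plain U-Net, and a coordinate-convolution variant with
    residual squeeze-excitation blocks and side-output fusion) under L1, L2
    or smooth-L1 losses, evaluates them with a grouped train/test protocol
    (MAE, MSE, NRMSE), and measures individual and mean fiber diameters from
    predicted maps via medial-axis ridge extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
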