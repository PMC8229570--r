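Package: imtr
Title: Ultra-Wideband Microwave Radar Imaging of Breast and Skin Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for confocal ultra-wideband (UWB)
    microwave imaging of small tumors in layered breast/skin phantoms. A 2-D
    finite-difference time-domain (FDTD) solver with convolutional perfectly
    matched layers generates multistatic radar traces from synthetic dielectric
    phantoms; an analytic Born point-scatterer model provides an independent
    forward oracle. The improved modified time-reversal (IMTR) preprocessing
    chain (calibration, early-content removal, pairwise multiplication,
    temporal averaging, time gating, Gaussian windowing) feeds four image
    reconstruction algorithms: modified weighted delay-and-sum,
    delay-multiply-and-sum, time reversal (numeric re-injection and
    synthetic-aperture backprojection), and IMTR pair-delay backprojection.
    Reconstructions are scored with structural similarity (SSIM), mean squared
    error, localization error, and empirical point-spread-function resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
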