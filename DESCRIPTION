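Package: nirscart
Title: Arthroscopic Near-Infrared Spectroscopy Analysis of Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for relating arthroscopic near-infrared (NIR) diffuse
    reflectance spectra of articular cartilage to tissue reference properties
    (thickness, proteoglycan content and collagen orientation angle). The
    package implements dual-detector Savitzky-Golay derivative preprocessing,
    outlier rejection of non-contact in vivo spectra via a minimum volume
    enclosing ellipsoid in principal-component score space, depth-profile
    reference extraction, animal-level rank-paired cross-validation, and an
    ensemble of small one-dimensional convolutional and dense neural networks
    trained with the Adam optimizer. A synthetic cohort generator with a
    parametric spectral forward model makes the full pipeline testable
    end-to-end without access to measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
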