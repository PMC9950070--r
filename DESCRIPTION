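Package: rbcmorph
Title: Morphology Classification, Tracking and Morphometry of Stored Red Blood Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@rbcmorph.org", role = c("aut", "cre"))
Description: An open image-analysis toolkit for bright-field microscopy of
    stored red blood cells. Segments cells by adaptive thresholding with
    watershed splitting (or a two-stage well/cell pathway with a pluggable
    pixel classifier), classifies each cell into seven morphology classes
    (discocyte through spherocyte, plus stomatocyte) with an ensemble of
    independently trained members combined by unweighted softmax averaging,
    evaluates calibration with reliability diagrams and expected/maximum
    calibration error, tracks individual cells through time with a
    constant-velocity Kalman filter and Hungarian assignment, and summarises
    effective-diameter distributions per class with bias-corrected bootstrap
    confidence intervals, Cohen's d and common-language effect sizes. Ships a
    seeded synthetic-scene generator so the full pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
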