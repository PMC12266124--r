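Package: mtukit
Title: Design, Simulation and Quantification of Muscle-Tendon-Unit Bioactuators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for 3D-bioprinted muscle-tendon-unit (MTU)
    bioactuators. Parameterizes compact and sparse (bridged) MTU designs,
    builds labelled hexahedral meshes and simulates prescribed-strain
    contraction with a corotational finite-element model, including the
    maximum-deformation metric and design sweeps over bridge count and width.
    Quantifies contractility from grayscale video via dense optical flow:
    directional alignment at a chosen contraction angle, volumetric contractile
    kinetic energy, void segmentation and image-subtraction displacement.
    Fits tissue mechanics from Hertzian spherical microindentation and tensile
    curves, and computes myotube morphometry (fusion index, shift angle,
    width, texture variance). A synthetic-data generator with known ground
    truth (textured videos, indentation and tensile curves, labelled
    morphometry scenes) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    tiff,
    EBImage,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
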