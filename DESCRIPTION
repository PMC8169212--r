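Package: mesotissue
Title: Mesoscale Morphometrics of Dual-Circulation Exchange Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional characterization of porous exchange tissue
    imaged by micro-CT, exercised on synthetic volumes. Provides multi-view
    2.5D segmentation fusion with agreement voting, centerline skeleton
    morphometrics of branching vessel networks (diameter, length,
    tortuosity), watershed pore separation with ball-and-stick pore-throat
    networks and percolation bottleneck analysis, voxelized Stokes flow with
    Darcy permeability and streamline tortuosity, virtual 2D stereology
    (point and line-intercept counting), and scale-dependent uncertainty
    quantification of morphological metrics (ROI fluctuation scaling and
    two-point autocorrelation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
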