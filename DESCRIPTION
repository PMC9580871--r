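Package: punctakit
Title: Quantification of Biomolecular Condensates in Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and segments fluorescently-labeled biomolecular
    condensates ("puncta") inside segmented cells or nuclei in 3D
    multi-channel fluorescence z-stacks. Provides data staging from
    per-slice TIFF files, region-of-interest segmentation with a pluggable
    backend and 2D-to-3D layer merging, multiscale Laplacian-of-Gaussian
    puncta detection with background-aware filtering and seeded-watershed
    segmentation, per-punctum and per-ROI measurement tables including
    colocalization statistics, derivation of thermodynamic parameters of
    liquid-liquid phase separation (partition coefficient, Gibbs free
    energy of transfer, volume and mole fractions), mixed-effects
    comparison of conditions, and a synthetic-stack simulator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    lme4,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
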