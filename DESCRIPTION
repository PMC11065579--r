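Package: ecmquant
Title: Quantification of Extracellular Matrix Architecture, Spectra, and
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reusable quantification pipeline for fibrous extracellular
    matrix characterization: fiber-network architecture extraction from
    electron micrographs (segmentation, skeletonization, network
    descriptors), Raman spectral preprocessing (Savitzky-Golay smoothing,
    iterative modified-polynomial fluorescence background subtraction,
    min-max normalization, collagen/lipid band ratios, principal
    components), Hertz-model stiffness fitting of AFM force-distance
    curves, conversion of oscillatory rheology moduli to Young's modulus,
    and cell-level morphology, colocalization, invasion, and intensity
    metrics.  Includes seeded synthetic-data generators that emit every
    input type together with its ground truth, so each stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
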