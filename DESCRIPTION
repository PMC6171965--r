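Package: cortexsim
Title: Agent-Based Simulation of Actomyosin Aster Formation in the Cell Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional agent-based model of the cortical actomyosin
    network: rigid polar actin filaments remodelled by two-headed Hookean
    myosin motors under slender-rod viscous drag, with stochastic motor
    binding, plus-end directed walking, filament turnover, passive
    angle-restricted cross-linkers, and spatial tethering inside an open
    hexagonal domain. Includes the analysis toolkit used to characterise the
    emergent aster phenomenology: plus-end divergence maps and aster
    detection, synthetic fluorescence rendering, kymographs, region-of-
    interest intensity traces, coarse-grained hexagon segmentation, motor
    force statistics, plus-end connectedness, and work-energy accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    EBImage,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
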