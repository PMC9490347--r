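Package: filbuckle
Title: Elastic Instabilities in Biological Filament Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal discrete model of planar elastic filament bundles
    coupled by a Hookean spring matrix, for studying global buckling,
    pinching and internal (high-wavemode) collapse under axial and lateral
    loads. Provides the bundle energy functional with analytic gradients,
    L-BFGS energy minimization from archetypal seeds, deformation-mode
    classification, phase-space sweeps over load and sheath-stiffness
    parameters, internal interaction-pressure maps, and an analytic
    triangular-kink criterion for the internal buckling load together with
    numerical critical-load location and prefactor fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    readr,
    ggplot2,
    jsonlite,
    rlang,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
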