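Package: excitonet
Title: Exciton Transfer Dynamics and Neural-Network Surrogates for
    Light-Harvesting Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying excitation energy transfer (EET) in
    pigment-protein complexes described by Frenkel exciton Hamiltonians.
    Provides two open-quantum-system engines with phenomenological trapping
    and exciton loss: hierarchical equations of motion (HEOM) with a
    Drude-Lorentz bath in the high-temperature approximation, and a secular
    Redfield master equation in the exciton basis. On top of the engines the
    package builds databases of transfer times and efficiencies for randomly
    sampled Hamiltonians, selects diverse training sets by farthest-point
    sampling in a PCA-reduced feature space, trains multi-layer perceptron
    surrogates that predict transfer properties directly from the
    Hamiltonian, and tunes their hyperparameters by Gaussian-process
    Bayesian optimization.
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
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    lhs,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
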