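Package: csif
Title: Four-State Analysis of Ligand-Binding Pathways from CPMG Relaxation
    Dispersion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to resolve conformational-selection and induced-fit
    ligand-binding pathways from 15N CPMG relaxation dispersion data.
    Implements the Carver-Richards closed form for two-state chemical
    exchange, a general N-state Bloch-McConnell propagator for forward
    simulation of dispersion curves, two-state and global four-state
    least-squares fitting across a ligand titration with grid-search
    initialization and Monte-Carlo error estimates, and kinetic
    post-analysis of the fitted exchange network: microscopic rate
    constants, equilibrium state populations, pathway fluxes via
    waiting-time sums, flux crossover concentrations, and the
    diffusion-limited on-rate. Includes a synthetic-data generator that
    emulates a titration study of lactose binding to the galectin-3
    carbohydrate-recognition domain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
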