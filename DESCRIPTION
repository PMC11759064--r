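Package: cgrheo
Title: Coarse-Grained Condensate Rheology and Aging Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builders, Langevin dynamics, and viscoelastic analysis for
    coarse-grained models of biomolecular condensates. Generates bead-spring
    melts, solvated mixtures, sticker-spacer chains and cross-linked gels in
    reduced Lennard-Jones units; integrates Langevin dynamics with optional
    oscillatory Lees-Edwards shear; and turns stress time series into
    relaxation moduli via the Green-Kubo stress-autocorrelation estimator
    with multi-tau correlation, generalized Maxwell fits, storage/loss
    spectra, crossover frequencies and Maxwell-fluid versus Kelvin-Voigt
    classification. Includes slab coexistence and critical-point fitting,
    chain observables (persistence length, radius of gyration, mean-squared
    displacement), a residue-level hydropathy-scaled chain model with
    explicit solvent, and a nonequilibrium solvent-evaporation protocol for
    studying corona-shell formation during condensate aging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
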