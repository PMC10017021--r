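Package: qcembed
Title: Projection-Based Wavefunction-in-DFT Embedding with a DMRG Solver
Version: 0.1.0
Authors@R:
    person("qcembed", "developers", email = "qcembed@example.org",
           role = c("aut", "cre"))
Description: Quantum embedding toolkit for molecules with a strongly
    correlated fragment. A full-system Hartree-Fock or Kohn-Sham DFT
    calculation is partitioned into an active subsystem and its
    environment by the SPADE singular-value procedure, the virtual space
    is truncated by concentric localization, and the active subsystem is
    solved at the wavefunction level (determinant FCI or a two-site
    matrix-product-state DMRG solver with dynamical block state
    selection) inside a projection-based DFT embedding potential with a
    level-shift projector. Includes a self-contained Gaussian integral
    engine (s, p, d shells), restricted HF/KS-DFT with several
    functionals, FCIDUMP input/output, and deterministic molecular
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
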