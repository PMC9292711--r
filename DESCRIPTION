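Package: sysdrift
Title: Linear Gene-Network Models of Developmental System Drift and
    Hybrid Incompatibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models gene regulatory networks as linear time-invariant
    dynamical systems in which the hidden molecular state (the
    "kryptotype") is driven by environmental input and the phenotype is a
    linear read-out. Provides exact tests of phenotypic equivalence via
    Markov parameters, the Kalman decomposition and minimal realization,
    the neutral tangent directions of the equivalence set, diploid
    genetics over system coefficients (meiosis with unlinked loci, F1/F2
    crosses, X-linked loci with dosage compensation), a weighted
    L2 distance-to-optimum functional with quadrature, finite-horizon
    Gramian and Lyapunov evaluators, hybrid-breakdown scaling
    experiments, and a neutral system-drift simulator for diverging
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
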