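Package: bcrwave
Title: Bistable Reaction-Diffusion Simulator of B-Cell Receptor Activation Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mutual activation of B-cell receptors (BCR) and
    Src-family kinases as a bistable reaction-diffusion system on a spherical
    cell, in three tiers: a well-mixed ODE limit with bifurcation and
    bistability-range analysis, a one-dimensional membrane model on the sphere
    (kinase confined to the membrane), and an axisymmetric cytosolic model on a
    spherical shell with a nonlinear Robin boundary condition coupling membrane
    receptors to diffusing kinase. Includes receptor-cluster generators,
    critical-cluster-size bisection, front-speed measurement, critical
    dephosphorylation-rate analysis, and a displaced-nucleus geometry, together
    with experiment drivers that tabulate activation outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    digest,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
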