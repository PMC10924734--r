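Package: spinedrift
Title: Electrodiffusive Cable-Equation Modelling of Dendritic Spines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coupled dynamics of membrane potential and
    intracellular ion concentrations (sodium, potassium, chloride) in
    dendritic spines using an electrodiffusive extension of the cable
    equation.  Axial currents are driven both by the electric field (drift)
    and by chemical-potential gradients (diffusion); the membrane potential
    is derived from the net ionic charge through the membrane capacitance.
    The coupled species equations are integrated with an explicit
    finite-difference scheme (compiled inner loop) with harmonic-mean
    interface conductivities, Neumann synaptic and Dirichlet dendritic
    boundary conditions.  Includes analysis tools for drift/diffusion
    current decomposition, cumulative and voltage-divider neck resistance,
    depolarization-boost metrics, sodium decay-time fitting, a
    voltage-dependent NMDAR conductance readout, declarative experiment
    protocols, a YAML configuration schema and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
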