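Package: angiomol
Title: Method-of-Lines Simulation of an Oxygen-Coupled Tumor Angiogenesis Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional five-field continuum model of tumor-induced
    angiogenesis (endothelial cells, protease, inhibitor, extracellular matrix and
    oxygen) coupled through haptotaxis, chemotaxis, Michaelis-Menten oxygen kinetics
    and a fixed tumor-angiogenic-factor profile. Space is discretized by second-order
    finite differences with Neumann-consistent one-sided boundary stencils and the
    semi-discrete system is advanced with classical fourth-order Runge-Kutta.
    Includes stability-limit calculators (diffusion, CFL and invariant-region
    restrictions), manufactured-solution convergence studies in space and time,
    invariant-region and energy monitoring, a physiological angiogenesis scenario,
    parameter sensitivity sweeps, and plain-text snapshot/report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
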