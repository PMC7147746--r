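Package: ictalwave
Title: Spatially Extended Epileptor-2 Simulation of Seizure Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the generation and spatial propagation of epileptic
    ictal discharges on a two-dimensional cortical sheet with a spatially
    extended variant of the Epileptor-2 neural-mass model. Two competing
    propagation mechanisms are implemented: extracellular potassium
    diffusion and axo-dendritic synaptic spread through an exponentially
    decaying connectivity kernel (a screened-Poisson coupling), singly or
    combined. The stochastic reaction-diffusion system is integrated with
    an explicit Euler-Maruyama scheme on a regular grid with Neumann
    boundaries; lesions of the synaptic connectivity can be imposed.
    Includes an adaptive quadratic integrate-and-fire neuron-observer,
    and analysis tools for ictal-discharge detection, potassium-wavefront
    speed estimation, space-time burst diagrams, and burst synchrony.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    yaml,
    jsonlite,
    Matrix,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
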