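Package: cleftsim
Title: Monte Carlo Electrodiffusion of Glutamate in the Synaptic Cleft
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulator of charged neurotransmitter (glutamate)
    diffusing in the narrow synaptic cleft of the cerebellar mossy-fiber to
    granule-cell synapse under the electric field generated by its own
    receptor currents. Couples Brownian particle dynamics with drift derived
    from a modified-Bessel radial voltage profile, mean-field Markov kinetics
    of AMPA, NMDA and perisynaptic mGluR1 receptors (including competitive
    antagonist transforms and Q10 temperature scaling), perturbation of
    pre-equilibrated intracleft ions, and Hodgkin-Huxley or template
    postsynaptic action potentials. Ships virtual-experiment protocols
    (voltage sweeps, spike-release pairing, antagonist and driving-force
    manipulations, timestep convergence) and trace analysis utilities
    (exponential decay fits, tail fold-changes, charge transfer).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    yaml,
    optparse
Config/testthat/edition: 3
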