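Package: izhnet
Title: Spiking Neuronal Networks Under Graded Changes in Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spontaneous activity in networks of
    stochastic Izhikevich neurons coupled by conductance-based synapses.
    Builds synthetic weighted directed networks with long-tailed per-neuron
    outgoing-weight distributions, together with degree- and
    weight-preserving surrogate networks (Gaussian-weight, column-shuffled,
    row-shuffled). Applies graded uniform suppression or enhancement of
    inhibitory synaptic weights and quantifies the per-neuron firing-rate
    responses, the network-average rate change, and bursting as bimodality
    of the pooled log inter-spike-interval distribution. Includes a fast
    compiled Euler-Maruyama integrator, closed-form conductance oracles,
    spike-train fixture generators, text-based file formats for networks,
    spike trains and configurations, and a command-line driver for full
    suppression-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
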