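Package: plastinet
Title: Spiking Recurrent Networks with Orchestrated Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for conductance-based integrate-and-fire
    networks in which excitatory synapses are governed by an orchestrated
    combination of triplet spike-timing-dependent plasticity, burst-gated
    heterosynaptic plasticity relative to a slowly consolidating reference
    weight, transmitter-induced potentiation and Tsodyks-Markram short-term
    plasticity, while inhibitory synapses follow a globally modulated
    spike-timing-dependent rule.  Includes the induction and stimulation
    protocols used to probe cell-assembly formation, memory recall and the
    bistable fixed-point structure of the synaptic dynamics, together with
    spike-train and weight-matrix analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
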