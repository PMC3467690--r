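Package: spikechain
Title: Self-Organizing Synfire-Chain Recognizers for Spatio-Temporal Spike Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a small winner-takes-all network of leaky
    integrate-and-fire neurons with alpha-function synapses whose
    feed-forward and lateral connections are shaped by additive exponential
    spike-timing-dependent plasticity (STDP, nearest-neighbor or all-to-all
    pairing). Driven by a frozen 50-ms spatio-temporal spike pattern
    embedded in statistically identical Poisson noise, the excitatory
    neurons self-organize into directed chains in which each neuron
    recognizes a segment of the pattern and the terminal ("accepting")
    neuron fires only when the whole pattern is presented in order --- a
    simple neural finite-state recognizer. Includes the stimulus generator,
    a fast compiled network simulator, chain-graph extraction and
    evaluation criteria, lateral-weight-bound sweeps, multi-pattern and
    chain-concatenation training protocols, and a speed-invariance probe.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
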