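Package: ca3assembly
Title: Cell Assembly Formation and Pattern Completion in a Spiking Network
    Model of Hippocampal CA3
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, trains, and tests a multi-type spiking neural network
    model of hippocampal area CA3. Neurons follow the nine-parameter
    Izhikevich dynamical-systems framework and synapses the five-parameter
    Tsodyks-Markram short-term plasticity model; recurrent excitatory
    synapses learn under a symmetric spike-timing-dependent plasticity rule.
    The package generates networks at full or reduced scale from declarative
    configurations, drives them with theta-nested gamma stimulation
    protocols, applies divisive synaptic downscaling between training and
    testing, and quantifies auto-association and pattern completion with
    signal-to-noise, saturation, and Pearson-correlation reconstruction
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
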