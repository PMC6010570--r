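Package: stdpnet
Title: Event-Driven Spiking Convolutional Networks with Unsupervised STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven simulator for deep spiking convolutional networks
    of integrate-and-fire neurons that learn hierarchical features with
    unsupervised spike-timing dependent plasticity (STDP) in all layers
    simultaneously. Implements dual-accumulator neurons that decouple
    winner-take-all learning competition from spike propagation, a bounded
    exponential STDP rule driven purely by relative spike timing (no leak, no
    refractory period, no per-stimulus resets, no homeostasis), rate encoding
    of grayscale images into noisy periodic spike trains, relay pooling, and an
    unsupervised spike-count labeling and classification readout. The network
    dynamics are timescale invariant: uniformly rescaling all input event times
    leaves spike sequences and learned weights unchanged.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
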