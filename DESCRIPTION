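Package: edn
Title: Error Driven Neurogenesis Networks for One-Shot Online Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grows networks of kernel-memory neurons in response to
    prediction errors. Each neuron stores one input pattern on its
    afferent synapses using a triangle kernel and carries signed weights
    to the outputs, so a single presentation of a sample is enough to
    store and immediately use it. Supports online classification with
    surprise-driven input selection, regression through paired
    real/inverse output coding, and reinforcement learning with
    failure-window neurogenesis and reward-based pruning, demonstrated on
    a built-in cart-pole environment. Trained networks are fully
    introspectable: per-class expectations, signed receptive fields and
    decision-boundary rasters can be extracted from the stored synapse
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    caret,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
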