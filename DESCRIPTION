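Package: eqprop
Title: Equilibrium Propagation for Convergent Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains convergent recurrent neural networks with Equilibrium
    Propagation (EP), a two/three-phase learning algorithm whose weight
    updates are local in space and approach the gradients of
    Backpropagation Through Time (BPTT) as the nudging strength goes to
    zero. Implements the energy-like primitive and free/nudged relaxation
    dynamics for convolutional and fully connected layers with max
    pooling, the one-sided, random-sign and bias-cancelling symmetric
    gradient estimators, softmax-readout cross-entropy nudging,
    vector-field estimators with unidirectional forward/backward weights
    and the Kolen-Pollack-style shared update with leakage, a truncated
    BPTT oracle with per-timestep gradient-matching diagnostics, a full
    SGD training loop (per-layer learning rates, momentum, weight decay,
    cosine annealing, optional dropout), and seeded synthetic image tasks
    and network fixtures for desk-scale verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
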