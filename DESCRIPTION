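Package: tlrnet
Title: Three-Threshold Learning in Recurrent Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and theory for a recurrent network of binary excitatory
    neurons with global inhibitory feedback in which memory patterns are stored
    by a three-threshold synaptic plasticity rule (3TLR). The rule potentiates or
    depresses synapses from active presynaptic neurons depending on the position
    of the postsynaptic local field relative to three thresholds, requires no
    explicit error signal, and approaches the Gardner storage capacity bound
    under sign-constrained (excitatory) weights. The package provides pattern
    generators (random and category-correlated), the network dynamics and
    inhibition calibration, the 3TLR together with perceptron-rule and Hopfield
    baselines, basin-of-attraction and storage-capacity measurement protocols,
    post-learning connectivity statistics, and a replica-symmetric solver for
    the theoretical critical capacity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
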