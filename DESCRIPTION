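Package: wmcircuit
Title: Reward-Modulated Plasticity in Recurrent Working-Memory Circuits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a discrete-time recurrent network of binary threshold
    neurons that learns delayed-response and delayed-categorization working
    memory tasks through reward-modulated spike-timing-dependent plasticity
    (r-STDP) with eligibility traces, stabilised by homeostatic intrinsic
    plasticity and synaptic scaling. Provides the four task families (delayed
    response, delayed categorization, and two multi-task variants with
    disjoint or overlapping category boundaries), an incremental-delay
    training curriculum, ablation modes (frozen or reward-independent
    recurrent plasticity), and population analyses: depth of selectivity,
    selective fractions and multiplexing statistics, post-stimulus time
    histograms, principal-component trajectories, and connectivity-structure
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
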