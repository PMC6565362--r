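Package: mscann
Title: Concurrent Multisensory Integration and Segregation with Congruent
    and Opposite Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying concurrent multisensory integration and
    segregation of circular stimulus features (e.g. heading direction from
    visual and vestibular cues). Implements the von Mises Bayesian model of
    cue integration and cue-disparity computation, a decentralized
    two-module continuous attractor network with congruent and opposite
    neurons coupled by reciprocal connections and divisive normalization,
    population-vector decoding of bump positions, and ROC-based neurometric
    analyses (cue-disparity and heading discrimination, cumulative-Gaussian
    discrimination thresholds, combined-cue threshold prediction).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
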