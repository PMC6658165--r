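Package: matchRisk
Title: Experience-Based Variance Risk in a Dynamic Matching Task: Simulation
    and Neuronal Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the baited dynamic-probability matching task used to
    study experience-based economic risk, constructs subjective value and
    variance-risk decision variables from recency-weighted reward histories,
    fits and compares history-based and reinforcement-learning choice models,
    and implements a single-neuron and population analysis battery for
    risk coding: epoch regressions with standardized coefficients, angle
    classification of risk responses, stepwise and partial-F model tests,
    sliding-window regression with shuffle calibration and coding latencies,
    risk-updating contrasts, and pseudo-population decoding with linear
    support-vector-machine and nearest-neighbour classifiers. A synthetic
    Poisson spiking generator with configurable tuning provides ground truth
    for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    e1071,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
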