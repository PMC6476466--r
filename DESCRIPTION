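Package: patsep
Title: Temporal Pattern Separation Analysis for Neuronal Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify temporal pattern separation and convergence by
    single neurons under multiplexed neural codes. Generates ensembles of
    input spike trains with controlled pairwise similarity (correlated
    Poisson sets, rate-varying sets, fixed-rate bursty sets), simulates
    output sweeps with a stochastic input-to-output neuron model, and
    measures pairwise spike-train similarity with binned metrics (Pearson
    correlation, normalized dot product, scaling factor) across time scales
    as well as the binless SPIKE similarity. Includes firing-rate and
    burstiness features (Compactness, Occupancy, burst probability,
    Kullback-Leibler burstiness), parentage-aware pattern-separation graphs,
    Gini-mean-difference dispersion analysis, and the associated statistics
    (linear and parabolic fits, one-sample separation tests, separate-lines
    ANCOVA across conditions or cell types).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
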