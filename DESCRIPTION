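Package: wnet
Title: Weighted Phase-Lag-Index Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates weighted phase lag index (WPLI) functional
    connectivity from epoched multichannel EEG, builds proportionally
    thresholded graphs in binary and weight-preserving modes, computes
    binary and weighted graph-theoretical measures with random-surrogate
    normalization, quantifies the dependence of each measure on network
    density through Spearman bootstrap tests, power-law curve fits and a
    closed-form derivative-ratio criterion, and provides the cohort-level
    statistics used in EEG dementia studies: rank-based group tests with
    Holm-Bonferroni control, Mack-Skillings tests across threshold
    levels, network-based-statistic permutation components, edge-distance
    comparisons, clinical correlations, and a random-forest diagnostic
    classifier. A synthetic-cohort generator with planted band-specific
    connectivity effects makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
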