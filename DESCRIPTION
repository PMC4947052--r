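Package: measelect
Title: Stimulus-Selectivity Analysis for Microelectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("MEA", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-evoked responses of cultured
    neuronal networks recorded on planar microelectrode arrays (MEAs).
    Provides threshold-based extracellular spike detection on band-pass
    filtered traces, post-stimulus response feature extraction (binned
    spike-rate patterns, activation times, total spike counts) with
    activity and stationarity filters, a K-means misclassification
    "overlap" selectivity statistic with per-electrode/per-bin signatures,
    stimulus-site decoding with three classifiers (unsupervised K-means,
    nearest class centroid, cross-validated RBF support-vector machine),
    and a synthetic-recording generator with controllable ground-truth
    selectivity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    yaml,
    optparse
Config/testthat/edition: 3
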