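Package: ensemblelink
Title: Ensemble Co-Reactivation Analysis for Multi-Session Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline ensemble co-reactivation analysis for multi-session
    single-cell calcium recordings. Takes deconvolved event matrices and
    cross-session cell-match tables and provides population burst detection,
    ensemble (co-)participation statistics, time-lagged cross-correlations,
    offline and recall reactivation indices, encoding/recall population-vector
    correlations, linear-SVM context decoding with shuffled-label controls,
    EEG/EMG sleep scoring via Gaussian mixtures with sleep-state-resolved
    co-bursting, and chemogenetic tagging of putative inhibitory neurons.
    Includes a synthetic-experiment generator with planted ensembles, bursts,
    hypnograms and ground truth so every stage is testable without real data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    mclust,
    signal
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
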