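Package: conflictstop
Title: Conflict-Modulated Response Stopping: Race-Model Simulation, Group
    ICA, Temporal Decoding and Brain-Behavior Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a combined Simon and
    Stop-Signal task. Provides a staircase-tracked independent race model
    for behavioral sessions with stop-signal reaction time (SSRT)
    estimation by the mean method and cohort exclusion rules; a synthetic
    EEG epoch generator with known ground-truth source topographies; group
    independent component analysis (PCA reduction, fixed-point ICA,
    per-subject back-reconstruction); cross-condition component matching
    by topography correlation; per-component time-resolved and
    temporal-generalization decoding with a linear maximum-margin
    classifier; group-level cluster-based permutation inference against
    chance; and a leave-one-out feed-forward neural-network regression
    linking decoding strength to the congruency effect on SSRT.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
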