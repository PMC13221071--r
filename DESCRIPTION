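Package: goalsync
Title: Multi-Scale Analysis of Hippocampal-Orbitofrontal Coordination During Goal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-region (dorsal CA1 and medial
    orbitofrontal cortex) electrophysiology recorded while rodents learn
    daily-changing goal locations on a cheeseboard maze. Provides a session
    data model with plain-text serialization, occupancy-normalized rate maps
    and Skaggs spatial information, goal-overlap and reorganization
    classification of units, LFP band power and coupling metrics (same-
    frequency phase-locking value, n:m phase-phase coupling, normalized-
    entropy phase-amplitude modulation index), sharp-wave-ripple and theta-
    cycle detection, spike-to-theta phase locking, jitter-surrogate tested
    short-latency cross-correlogram coordination with per-reference FDR
    control and learning-trend classification, cell-assembly detection via
    Marchenko-Pastur thresholded PCA plus ICA, Gaussian naive Bayes
    population decoding with micro-average ROC-AUC and fixed-N replacement
    controls, piecewise-linear breakpoint fitting of learning curves, a
    short-term synaptic plasticity recurrent-network navigation model, and a
    synthetic session generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
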