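Package: sleepHMM
Title: Unsupervised Sleep Staging from EEG/EMG with Two-Stage k-Means and
    a Discretized-Observation Hidden Markov Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for unsupervised segmentation of rodent sleep from
    two-channel EEG/EMG recordings. Band-limited power features (EMG
    r.m.s., EEG delta/theta and high/low power ratios) are extracted in
    fixed epochs, clustered into Wake, NREM and REM by a two-stage k-means
    procedure, and vector-quantized onto a small codebook of feature-space
    centroids. A three-state hidden Markov model with discretized
    observations is initialized from the cluster memberships, optionally
    refined by Baum-Welch, and decoded with the Viterbi algorithm to
    produce hypnograms. Sleep metrics (percent time, bout number, mean
    bout duration) and scorer-agreement statistics (confusion matrices,
    sensitivity/specificity, Wilcoxon signed-rank and Spearman
    comparisons) are computed from the decoded state sequences. A
    synthetic-data module generates ground-truthed hypnograms, features
    and raw signals with the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
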