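Package: odorvalence
Title: Valence and Identity Coding Analysis for Olfactory Conditioning Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing trial-structured
    single-neuron calcium fluorescence recorded during olfactory classical
    conditioning, built to ask whether a neural population encodes the reward
    contingency (valence) of an odor cue or its chemical identity. Provides
    moving-window Gaussian-mixture baseline estimation and dF/F computation,
    trial epoching, framewise Wilcoxon responsiveness testing with
    Holm-Bonferroni correction, single-neuron pairwise auROC decoding with
    permutation nulls, population cross-validated classifiers with
    cross-pair generalization matrices, PCA-restricted decoding,
    participation-ratio dimensionality with subsampling, distance-trajectory
    and clustering geometry, anticipatory-licking quantification, and
    variance-partitioning regressions that disentangle reward contingency
    from licking vigor. A synthetic-session generator emulates the
    conditioning paradigms (six-odor contingency-switch and lick/no-lick
    probabilistic reward) with ground-truth encoding classes so every stage
    is falsifiable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
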