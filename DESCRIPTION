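Package: memoraffect
Title: Memory-Induced Emotion Recognition from Wearable EEG with a
    1D Convolutional-Recurrent Feature Extractor and an Extreme
    Learning Machine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for four-quadrant (valence x arousal) emotion
    recognition from 14-channel wearable EEG recorded during cued
    autobiographical memory recall. Provides a synthetic cohort
    generator that reproduces the word-cued acquisition protocol and
    its self-annotation statistics, an ERP-locked preprocessing chain
    (downsampling, common average reference, 1-50 Hz band-pass,
    baseline-corrected 1-s epoching, z-scoring, Chebyshev type-II
    rhythm-band decomposition), a one-dimensional convolutional
    recurrent feature extractor (single channel-shared conv block with
    batch normalisation, ReLU, stride-1 max pooling and dropout,
    feeding a 32-unit LSTM) trained by backpropagation with Adam, an
    extreme learning machine classifier with closed-form least-squares
    output weights, and evaluation harnesses (repeated random splits,
    leave-one-subject-out, per-rhythm and classifier comparisons) with
    confusion-matrix derived metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    e1071,
    class,
    nnet,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
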