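Package: stresswave
Title: Wavelet-Decomposed EEG Stress Classification with Hybrid
    Convolutional-Recurrent Models
Version: 0.1.0
Authors@R:
    person("STEW Pipeline", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for binary mental-workload (stress vs.
    relax) classification from 14-channel, 128 Hz EEG recordings. Provides a
    seeded synthetic EEG generator emulating the plain-text layout of the
    STEW workload corpus, readers for that dialect, four-level Daubechies-4
    discrete wavelet decomposition with false-discovery-rate hard-threshold
    denoising and per-band reconstruction, non-overlapping window datasets
    with stratified splits and k-fold plans, six hybrid
    convolutional-recurrent classifiers (CNN front end feeding RNN, LSTM,
    GRU or BiLSTM stacks) trained by Adam on binary cross-entropy, and a
    confusion-matrix/ROC/cross-validation evaluation suite with columnar
    text exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
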