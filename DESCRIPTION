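Package: rcnneeg
Title: Residual 1-D Convolutional and Independently Recurrent Networks for
    Epileptic EEG Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic recognition of epileptic
    electroencephalogram (EEG) states from single-channel recordings.
    Provides readers and writers for plain-text single-channel EEG records
    and seizure annotation tables, fixed-length window segmentation,
    rule-based derivation of preictal/ictal/interictal periods from
    annotated seizures, a seeded synthetic EEG generator with class-distinct
    spectral structure, and a from-scratch residual 1-D convolutional
    network combined with stacked independently recurrent (indRNN) layers,
    trained by mini-batch stochastic gradient descent through compiled
    single-precision kernels. Includes stratified k-fold cross-validation
    with sensitivity/specificity/accuracy reporting and a small command-line
    interface for simulation, training and streaming prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
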