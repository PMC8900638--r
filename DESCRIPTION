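Package: dynergy
Title: Dynamic Energy Features and Bi-LSTM Classification for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Dynergy", "Developers", email = "dynergy@example.org", role = c("aut", "cre"))
Description: Projects multichannel EEG onto a region-weighted energy sequence,
    extracts a windowed dynamic feature set (time-domain statistics, Hjorth and
    autoregressive-spectrum frequency features, approximate entropy, wavelet
    entropy and differential entropy), reduces it with a mutual-information
    eigendecomposition (MIPCA), and classifies window sequences with a
    bidirectional LSTM network trained by RMSprop. Includes EDF/CSV/HDF5 I/O,
    leave-one-subject-out and stratified k-fold evaluation protocols, an RBF
    C-SVC baseline, and a synthetic EEG generator with controllable
    class-dependent band power so the full pipeline is testable without
    access-restricted corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
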