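Package: hrvstager
Title: Sleep Stage Classification from Heart Rate Variability with
    Bidirectional LSTM Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic four-class sleep staging (wake, REM, N1/N2, N3) from
    inter-beat-interval (RR) series. Computes a 132-feature heart-rate
    variability battery per 30-second epoch (time-domain statistics,
    detrended fluctuation analysis, Welch and autoregressive spectral
    measures, multiscale sample entropy, cardiorespiratory phase
    synchronization, Teager energy on empirical-mode-decomposed signals,
    and visibility-graph descriptors), classifies whole-night feature
    sequences with a bidirectional LSTM trained on soft multi-annotator
    labels, and evaluates per-night agreement (Cohen's kappa, accuracy,
    per-stage metrics) with demographic subgroup statistics. Includes a
    synthetic whole-night cohort simulator with stage-dependent cardiac
    dynamics so the full pipeline can be exercised without access to
    clinical polysomnography data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
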