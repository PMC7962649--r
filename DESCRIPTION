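Package: ecgacgan
Title: Class-Conditional Synthetic ECG Cycles and Ensemble User Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrocardiogram (ECG) biometrics when enrollment and
    probe recordings differ in length. Simulates labelled multi-subject,
    multi-state single-lead ECG recordings with known R-peak ground truth;
    preprocesses them (baseline high-pass, powerline notch, Pan-Tompkins QRS
    detection, cycle segmentation); trains an auxiliary-classifier generative
    adversarial network (ACGAN) of one-dimensional convolutions to synthesize
    per-subject heartbeat cycles; scores generated cycles with cosine
    similarity and a cross-correlation Euclidean distance; and identifies
    users with a parallel ensemble of one-dimensional convolutional networks
    whose top members are fused and retrained. Includes an experiment driver
    that compares recognition accuracy across comparison templates mixing
    real, repeated, and synthetic cycles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
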