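Package: ionmqc
Title: Automated Labelling and Quality Control of Intraoperative
    Neuromonitoring EMG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quality control of intraoperative neuromonitoring
    (IONM) electromyography from thyroid and parathyroid surgery. Reads and
    writes the C2 Xplore per-operation CSV dialect (1410 columns per evoked
    signal), simulates complete synthetic surgeries with ground-truth labels,
    extracts fixed-width feature matrices (downsampled waveform segment plus
    whole-operation temporospatial context), trains a multitask 1-D
    convolutional-recurrent network with three softmax heads (nerve, side,
    stimulation time point), quantifies per-prediction uncertainty with Monte
    Carlo dropout calibrated against the training-set uncertainty
    distribution, and flags suspected mislabelled signals for manual review.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
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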