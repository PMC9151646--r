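Package: swaylab
Title: Multimodal Postural-Control Biomarkers for Concussion Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and statistical analysis for a multimodal
    postural-control protocol combining centre-of-pressure (CoP) stabilograms,
    64-channel EEG, lower-limb surface EMG, and heart rate, recorded around a
    platform-perturbation task with identical quiet-stance phases before (PRE)
    and after (POST) the perturbation. Implements the full stabilogram feature
    battery (path length, sway distances, 95% confidence ellipse, mean
    velocity, extreme-point magnitudes, sample and multiscale entropy,
    spectral power-law exponent), Welch relative EEG band powers with
    electrode-wise paired tests under Benjamini-Hochberg FDR correction, EMG
    spectral descriptors (total power, biased kurtosis and skewness, median
    frequency), POST-minus-PRE differencing, rank-based group statistics, and
    cross-validated classification of concussion status from combined
    questionnaire and biosignal features. A deterministic synthetic cohort
    generator with configurable planted group effects makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    readr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
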