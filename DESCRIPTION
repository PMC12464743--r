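Package: physiorecon
Title: Joint Reconstruction of Respiration Variation and Heart Rate from
    fMRI Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing low-frequency peripheral physiology in fMRI.
    Extracts frame-aligned respiration-variation (RV) and heart-rate (HR)
    series from raw respiration-belt and pulse-oximetry waveforms with
    automated quality control, reduces 4D fMRI volumes to atlas-parcel time
    series, and jointly reconstructs RV and HR from the parcel signals with
    a bidirectional LSTM trained under subject-wise cross-validation. Also
    provides respiration/cardiac response-function regressors with time and
    dispersion derivatives, percent-variance-explained maps, nuisance
    projection for functional-connectivity analyses, and a seeded forward
    simulator of coupled brain-body dynamics for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
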