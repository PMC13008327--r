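Package: bpvar
Title: Blood-Pressure Variability Features and Haemorrhagic-Transformation Risk Modelling
Version: 0.1.0
Authors@R: person("BPV", "Maintainers", email = "maintainers@bpvar.org", role = c("aut", "cre"))
Description: Extracts short-timescale blood-pressure variability features from
    paired continuous (1-min finger-cuff) and intermittent (scheduled arm-cuff)
    post-thrombectomy recordings: quality control with artefact masking and
    Gaussian-filter gap imputation, statistical dispersion features, and
    discrete-wavelet-transform band energies over dyadic oscillation-period
    bands. Quantifies the association of each feature with radiological
    haemorrhagic transformation via logistic regression (odds ratio per 1 SD,
    univariable and covariate-adjusted) and compares the predictive value of
    the two monitoring modalities with stratified 10-fold cross-validated
    AUC-ROC and average precision. Includes a synthetic cohort generator with
    closed-form band energies for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
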