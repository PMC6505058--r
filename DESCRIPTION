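Package: cisforest
Title: Lesion Shape Radiomics and Oblique Random Forests for Predicting
    Conversion from Clinically Isolated Syndrome to Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts conversion from clinically isolated syndrome (CIS) to
    multiple sclerosis from baseline FLAIR lesion masks. Extracts per-lesion
    3D shape features (marching-cubes surface area, Wadell sphericity,
    surface-volume ratio) and intensity-histogram features (skewness,
    kurtosis, Shannon entropy), aggregates them into fixed-length per-patient
    descriptors, and classifies patients with an oblique random forest whose
    node splits are learned by L2-regularised least squares. Includes a
    McDonald-2010 dissemination-in-space rule as a clinical benchmark, a
    stratified cross-validation harness, a full diagnostic-statistics suite
    (Clopper-Pearson, logit predictive-value and Glas diagnostic-odds-ratio
    confidence intervals, the Brodersen balanced-accuracy posterior interval,
    exact McNemar test), and a reproducible synthetic lesion-cohort generator
    for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
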