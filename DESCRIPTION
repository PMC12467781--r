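Package: sersdx
Title: Serum SERS Spectral Processing and PLS-SVM Diagnostic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for auxiliary-screening analyses of serum surface-enhanced
    Raman scattering (SERS) spectra. Provides a seeded synthetic-cohort
    generator with Lorentzian band templates and group effect profiles,
    iterative modified-polynomial fluorescence-baseline removal (Vancouver
    Raman Algorithm), integrated-area normalization and replicate averaging,
    band-level group comparisons routed through a normality/homogeneity
    decision tree, substrate-uniformity quality control (relative standard
    deviation, enhancement factor), and a PLS + RBF-SVM classification
    workflow with MSEP/adjusted-Wold component selection, stratified
    cross-validated grid search, confusion-matrix metrics and ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
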