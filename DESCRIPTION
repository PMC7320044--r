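Package: ramanmap
Title: Chemometric Analysis of Raman Hyperspectral Tissue Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discriminating tissue classes in Raman hyperspectral
    maps, as used to separate normal oesophageal squamous epithelium or
    Barrett's oesophagus from oesophageal adenocarcinoma. Implements the full
    chemometric chain: map unfolding, Savitzky-Golay smoothing, automatic
    weighted least squares (AWLS) baseline correction, Kennard-Stone
    training/validation splitting, principal component analysis followed by
    linear discriminant analysis with Mahalanobis distances (PCA-LDA),
    venetian-blinds cross-validation for component selection, classification
    figures of merit, difference-between-mean biomarker band extraction, and
    PCA score/reconstruction map imaging. Ships a seeded synthetic two-class
    Raman map generator so every stage is testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
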