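Package: ftirqda
Title: Chemometric Discrimination of ATR-FTIR Tissue Spectra with
    Quadratic Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classification pipeline for attenuated total reflectance
    Fourier-transform infrared (ATR-FTIR) absorbance spectra of tissue,
    covering the six ordered stages of oesophageal transformation to
    adenocarcinoma. Implements fingerprint-region truncation, rubber-band
    (lower convex hull) baseline correction and amide-I peak normalisation;
    quadratic discriminant analysis on principal-component scores (PCA-QDA)
    or on wavenumbers chosen by the successive projections algorithm
    (SPA-QDA) or a genetic algorithm (GA-QDA) driven by a
    misclassification-risk cost function; Monte Carlo cross-validation with
    confusion matrices, sensitivity, specificity and F-score figures of
    merit; bootstrap misclassification probability; and Mann-Whitney
    confirmation of selected wavenumbers. Includes a synthetic six-class
    spectra generator for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
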