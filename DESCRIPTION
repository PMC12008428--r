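Package: octomics
Title: Unsupervised OCT Radiomics Subtyping of Diabetic Macular Edema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised stratification of diabetic macular edema
    (DME) eyes from optical coherence tomography (OCT) B-scan radiomics.
    Implements IBSI-style texture feature extraction (first-order, 2D shape,
    GLCM, GLRLM, GLSZM, GLDM, NGTDM) on filtered image derivatives (wavelet,
    Laplacian-of-Gaussian, logarithm, exponential, gradient, square root,
    square, LBP), permutation-calibrated principal component retention
    (Horn's parallel analysis), hybrid Ward/K-means clustering with elbow and
    consensus-CDF model selection, bootstrap and noise-injection cluster
    stability, a three-stage feature-selection cascade (collinearity pruning,
    ANOVA screening, Boruta), logistic outcome models with backward stepwise
    selection, and a synthetic OCT-like cohort generator so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    ranger,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
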