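Package: gmdbiplot
Title: Generalized Matrix Decomposition Biplots for Microbiome Ordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ordination of sample-by-taxon count tables under arbitrary
    positive semidefinite similarity kernels. Implements the generalized
    matrix decomposition (GMD), which factors a data matrix X as U S V'
    subject to U'HU = I and V'RV = I for sample and variable kernels H and
    R built, e.g., from UniFrac or patristic distances. Provides
    compositional preprocessing (centered log-ratio, relative abundance),
    Gower double-centering of squared dissimilarities with positive
    semidefinite repair, form and covariance biplot layouts with projection
    of future samples, the approximate-matrix-duality (AMD) comparison
    decomposition, a synthetic-kernel simulation framework with prescribed
    spectra, and leave-one-out logistic-regression AUC evaluation of 2-D
    layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
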