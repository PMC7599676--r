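Package: meningrisk
Title: Radiomic and Semantic Risk Stratification of Atypical Meningiomas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating quantitative (radiomic) and qualitative
    (semantic) imaging features of atypical meningiomas with tumor recurrence
    and progression-free survival. Implements 3D texture-matrix feature
    extraction (gray-level co-occurrence, run-length and size-zone matrices)
    from segmented MRI volumes, first-order and shape descriptors, wavelet and
    Laplacian-of-Gaussian filter channels, and the full statistical chain:
    univariate logistic screening with odds ratios, ROC analysis with
    Youden-index dichotomization, multivariate Cox proportional-hazards models,
    Kaplan-Meier estimation and log-rank testing. A synthetic-data module
    generates phantom tumor volumes and simulated patient cohorts under
    proportional hazards so every stage of the pipeline can be validated
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    RNifti,
    jsonlite,
    yaml,
    digest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
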