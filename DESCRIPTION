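Package: tavrisk
Title: Probabilistic Multimodal Outcome Prediction with Missing-Data
    Marginalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative probabilistic model for predicting a binary clinical
    outcome (all-cause mortality after transcatheter aortic valve replacement)
    from tabular patient characteristics and a volumetric CT-derived region of
    interest. Missing covariates, missing manual image measurements and fully
    missing images are handled by closed-form marginalization using a
    probit approximation of the logistic-Gaussian integral, rather than by
    imputation. Includes straightened-ROI extraction along a smoothing-spline
    aortic centerline, a pluggable volumetric feature extractor trained
    jointly with the probabilistic parameters by maximum likelihood,
    stratified cross-validated AUROC evaluation with predictor-importance
    analysis, and synthetic cohort and tube-phantom generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
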