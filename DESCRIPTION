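Package: ramanscreen
Title: Raman Spectral Classification for Melanoma Biopsy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deciding melanoma biopsy recommendations
    from in vivo Raman spectra of pigmented skin lesions. Provides spectral
    preprocessing (cosmic-ray removal, Savitzky-Golay smoothing, iterative
    fifth-order modified-polynomial fluorescence-background subtraction,
    intensity-response correction, cropping to the 800-1790 1/cm fingerprint
    region and area normalization), principal component analysis with
    logistic regression under leave-one-lesion-out cross-validation and
    exhaustive principal-component subset search, per-lesion aggregation by
    the OR rule, ROC / number-needed-to-treat evaluation with a bootstrap
    confidence band, and a label-randomization null for the best-over-subsets
    AUROC. Includes a hierarchical synthetic Raman cohort generator built
    from tissue-constituent basis spectra so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
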