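Package: fbgpls
Title: Merged NIR and Process-Parameter PLS Modelling of Fluidized-Bed
    Granulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for inline particle-size and moisture
    prediction in fluidized-bed granulation. Provides a batch campaign data
    model for aligned NIR spectra (256 channels, 1081-2122 nm), process
    parameters and Eyecon-style granule-size percentiles; a synthetic
    campaign generator with injectable outlier batches; SNV and autoscaling
    preprocessing; a PLS1 engine with sequential, block and leave-one-out
    cross-validation; PCA/Mahalanobis/SIMCA and backward-batch-elimination
    (BBE-PLS) outlier screening; uninformative-variable-elimination
    (UVE-PLS) variable selection; and endpoint-prediction evaluation with
    RPD, RER, PRL and RPIQ summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    readr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    jsonlite,
    MASS,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
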