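Package: erkhistory
Title: Decoding ERK Signaling History from Fixed-Cell Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating single-cell ERK kinase activity dynamics,
    measured with a calibrated FRET biosensor, to endpoint immunofluorescence
    levels of ERK target genes (ETGs). Provides biosensor calibration from
    phos-tag anchor points, replicate batch correction in log space, pulse
    detection and a nine-feature summary of activity dynamics, forward
    prediction of ETG levels from activity traces (time-series and featurized
    linear models and a small 1-D convolutional network with
    integrated-gradients attribution), reverse inference of dynamic features
    from stain panels by cross-validated regression, a k-means prototype plus
    boosted multiclass classifier of signaling-history classes with hexagonal
    spatial aggregation, a delay differential equation simulator of ERK-driven
    gene expression used to bound what endpoint stains can encode, and a
    synthetic-data generator that emulates the statistical structure of
    combined live-cell and cyclic-immunofluorescence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    deSolve,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
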