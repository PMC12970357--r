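Package: wmhpheno
Title: Spatial Phenotyping of White Matter Hyperintensities
Version: 0.1.0
Authors@R:
    person("WMH", "Phenotyping Contributors", email = "wmhpheno@example.org",
           role = c("aut", "cre"))
Description: Identifies spatially defined subtypes of white matter
    hyperintensities (WMH) from 36-region bullseye representations of
    lesion load. Provides a Laplace-equation depth mapper that converts
    label volumes into lobe-by-layer regional volumes, ICV normalisation
    and feature engineering, a family of clustering engines (k-means,
    mini-batch k-means, Gaussian mixtures and subspace k-means),
    bootstrap Jaccard cluster-stability selection of the number of
    clusters, centroid-proximity risk-factor association with
    Benjamini-Hochberg correction, longitudinal progression labelling
    and gradient-boosted prediction of lesion progression, and a
    synthetic cohort generator so the whole pipeline is testable without
    access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
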