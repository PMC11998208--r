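Package: airwayclust
Title: Morphology-Based Clustering of Monopodial Airway Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions the segments of monopodial (asymmetrically branching)
    airway trees into morphological sub-compartments by Gaussian mixture
    modelling of lumen diameter and wall thickness with BIC model selection,
    benchmarks the partition against branching-based schemes (generations,
    orders, Strahler orders) using Davies-Bouldin and Dunn cluster-validity
    indices, and runs global and per-cluster two-group morphometry comparisons
    (Mann-Whitney U with rank-based effect size r). Includes a seeded
    generator of synthetic monopodial airway cohorts with known cluster
    archetypes and group effects for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
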