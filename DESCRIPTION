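Package: hemisnet
Title: Intra-Individual Hemispheric Structural Covariance Network Asymmetry
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construct per-subject, per-hemisphere cortical-thickness
    covariance networks from Desikan-Killiany regional thickness tables,
    compute binary graph-topological metrics (degree centrality, clustering,
    nodal global and local efficiency, and small-world indices normalized
    against degree-preserving null networks), form left-minus-right
    hemispheric differences, and test case-control effects on multi-site
    cohorts with random-intercept linear mixed models, label-swap permutation
    p-values and tiered multiple-testing correction. Includes a synthetic
    multi-site cohort generator with injectable hemisphere-specific coupling
    effects, descriptive edge-level analysis, and sparsity-sweep and
    model-variant sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
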