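Package: taugraph
Title: Band-Specific Envelope Connectomes and Tau-Associated Graph Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking regional Tau pathology (PET
    nondisplaceable binding potential) to neurophysiological network
    organisation measured with E/MEG. Implements band-limited amplitude
    envelope correlation connectomes from parcel time series with
    multivariate (symmetric-orthogonalization) source-leakage correction,
    proportionally thresholded weighted graphs, four nodal graph metrics
    (eigenvector centrality, weighted clustering, closeness centrality,
    Louvain participation coefficient) normalized against degree-preserving
    null ensembles, and permutation-corrected general linear models for
    group, Tau-burden and longitudinal contrasts. Ships a synthetic-cohort
    generator with known ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
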