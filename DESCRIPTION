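Package: netsweep
Title: Sparsity-Sweep Graph Analysis of Resting-State Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group-level graph-theoretical analysis of resting-state
    functional connectivity. Builds Fisher-z interregional connectivity
    matrices from ROI time series (detrending, ideal band-pass filtering,
    nuisance regression), thresholds them into binary networks over a sparsity
    sweep, computes global small-world and efficiency metrics plus nodal
    degree, efficiency and betweenness, normalizes small-world parameters
    against degree-matched Maslov-Sneppen random networks, summarizes each
    metric curve as an area under the curve, and performs nonparametric
    permutation group inference and training-duration correlations. Includes
    a synthetic two-group cohort generator with planted small-world covariance
    structure so the full pipeline runs without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
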