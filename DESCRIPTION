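Package: stimnet
Title: Stimulation-Responsive Networks in a Connectome-Based Whole-Brain Model
Version: 0.1.0
Authors@R:
    person("Jonas", "Weidner", email = "jweidner@example.org", role = c("aut", "cre"))
Description: Simulates focal stimulation of a whole-brain network of
    near-critical Andronov-Hopf oscillator nodes coupled by short-range
    Gaussian (homogeneous) connectivity on two spherical cortical meshes and
    by long-range delayed (heterogeneous) area-to-area connectivity.
    Decomposes the evoked energy dissipation into principal spatial patterns
    (dynamically responsive networks), clusters them across stimulation
    sites with the gap statistic, and matches them to resting-state-network
    masks using the Bhattacharyya coefficient with permutation statistics
    and Bonferroni-Holm correction.  Ships a synthetic-brain generator so
    the full pipeline runs without external connectome data, plus readers
    for connectome weight/tract-length matrices and surface meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    interp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
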