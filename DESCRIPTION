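Package: riccinet
Title: Ollivier-Ricci Curvature of Biological Networks from Node-Level Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Ollivier-Ricci curvature, an edge-level measure of
    network robustness, on undirected interaction networks weighted by
    node-level omics measurements (e.g. gene expression). Node weights
    define mass-action random-walk transition probabilities, which induce
    neighbor probability measures and (optionally) transformed edge
    lengths; curvature of an edge is one minus the Wasserstein-1 distance
    between the endpoint measures divided by their shortest-path distance.
    Provides per-sample edge curvature matrices over a cohort, differential
    (delta) curvature between samples or groups, CSV input/output in a
    simple feature-table plus adjacency-matrix format, synthetic fixture
    generators, an exact transportation-problem solver with an independent
    brute-force oracle, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    boot,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
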