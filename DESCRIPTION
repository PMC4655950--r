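Package: connectogen
Title: Generative Models of Spatially Embedded Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grows synthetic connectomes edge-by-edge under wiring rules that
    combine a geometric distance penalty with one of thirteen topological
    kernels (degree-, clustering- and homophily-based), scores synthetic
    networks against an observed network with an energy defined as the maximum
    of four Kolmogorov-Smirnov statistics (degree, clustering, betweenness
    centrality, edge length), and fits the wiring-rule exponents by a
    Voronoi-tessellation Monte Carlo search with an annealed sampling
    exponent. Includes cross-validation measures (global graph statistics,
    distance-dependent degree assortativity, per-node z-scores against
    best-fitting ensembles), a density-preserving uniform null model, and a
    synthetic-data generator so the whole pipeline is testable without
    imaging data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
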