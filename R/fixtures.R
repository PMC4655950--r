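#' Configuration for synthetic "observed" connectome fixtures
#'
#' Describes a fully synthetic target network with the structural
#' properties the growth model assumes: spatial embedding, roughly 10%
#' density and distance-dependent connectivity. The defaults mirror the
#' regime of a single-hemisphere human connectome at ~10% density
#' (n around 100, M around 500, seed about a tenth of M) with a
#' homophily-driven wiring rule at a mild distance penalty.
#'
#' @param n node count (>= 10).
#' @param density target connection density rho in (0, 1).
#' @param scheme coordinate scheme: `"shell"` (points on a sphere of
#'   radius `extent` mm, a crude cortical-sheet stand-in) or `"cube"`
#'   (uniform in a cube of side `2 * extent` mm).
#' @param rule generating wiring rule.
#' @param eta,gamma generating parameters.
#' @param epsilon kernel regularizer.
#' @param seed_edges number of seed edges (the `seed_edges`
#'   shortest-distance pairs); defaults to 10% of M.
#' @param extent spatial scale in mm (default 50).
#' @param rng_seed integer seed; every fixture is reproducible from its
#'   config alone.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n = 100, density = 0.1,
                           scheme = c("shell", "cube"), rule = "matching",
                           eta = -1.0, gamma = 0.4, epsilon = 1e-6,
                           seed_edges = NULL, extent = 50, rng_seed = 1) {
  scheme <- match.arg(scheme)
  if (n < 10) stop("fixture networks need at least 10 nodes")
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  M <- round(density * n * (n - 1) / 2)
  if (is.null(seed_edges)) seed_edges <- round(0.1 * M)
  if (seed_edges > n * (n - 1) / 2) stop("seed_edges exceeds available pairs")
  structure(list(n = n, density = density, scheme = scheme,
                 rule = match_rule(rule), eta = eta, gamma = gamma,
                 epsilon = epsilon, M = M, seed_edges = seed_edges,
                 extent = extent, rng_seed = rng_seed),
            class = "fixture_config")
}

#' Deterministic fixture coordinates
#'
#' Draws `n` distinct 3-D points under the config's scheme and seed.
#'
#' @param config a [fixture_config()].
#' @return `n x 3` coordinate matrix (mm).
#' @export
make_coords <- function(config) {
  set.seed(config$rng_seed)
  n <- config$n
  repeat {
    xyz <- switch(config$scheme,
                  shell = {
                    g <- matrix(stats::rnorm(3 * n), n, 3)
                    g / sqrt(rowSums(g^2)) * config$extent
                  },
                  cube = matrix(stats::runif(3 * n, 0, 2 * config$extent),
                                n, 3))
    D <- as.matrix(stats::dist(xyz))
    if (min(D[upper.tri(D)]) > 0) return(xyz) # coincident draws: retry
  }
}

#' Shortest-distance seed network
#'
#' Deterministic, data-free stand-in for a consensus seed: the
#' `seed_edge_count` shortest-distance node pairs (ties broken by pair
#' order). Being purely distance-based, it is invariant (up to
#' isomorphism) under node relabeling.
#'
#' @param coords coordinate matrix.
#' @param seed_edge_count number of seed edges.
#' @return A `spatial_graph`.
#' @export
make_seed_graph <- function(coords, seed_edge_count) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (seed_edge_count > n * (n - 1) / 2)
    stop("seed_edge_count exceeds the number of node pairs")
  A <- matrix(0, n, n)
  if (seed_edge_count > 0) {
    D <- euclidean_distances(coords)
    ut <- which(upper.tri(D))
    picked <- ut[order(D[ut])[seq_len(seed_edge_count)]]
    A[picked] <- 1
    A <- A + t(A)
  }
  spatial_graph(A, coords)
}

#' Generate a synthetic observed network
#'
#' Grows a ground-truth target with [grow_network()] at the config's rule
#' and parameters, to exactly `M = round(rho * n(n-1)/2)` edges. The
#' generating parameters are recorded in a `provenance` attribute so
#' parameter-recovery experiments know the truth by construction.
#'
#' @param config a [fixture_config()].
#' @return A `spatial_graph` with attribute `provenance` (named list).
#' @export
make_observed <- function(config) {
  coords <- make_coords(config)
  seed <- make_seed_graph(coords, config$seed_edges)
  params <- generative_params(eta = config$eta, gamma = config$gamma,
                              epsilon = config$epsilon, M = config$M)
  trace <- grow_network(seed, config$rule, params,
                        rng_seed = config$rng_seed + 1)
  g <- trace$graph
  attr(g, "provenance") <- list(
    n = config$n, density = config$density, scheme = config$scheme,
    rule = config$rule, eta = config$eta, gamma = config$gamma,
    epsilon = config$epsilon, M = config$M, seed_edges = config$seed_edges,
    extent = config$extent, rng_seed = config$rng_seed)
  g
}
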