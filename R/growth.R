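#' Parameters of the generative growth model
#'
#' @param eta distance exponent: `eta < 0` penalizes long connections,
#'   `eta > 0` favours them.
#' @param gamma topology exponent scaling the influence of the wiring-rule
#'   kernel; ignored by the pure geometric rule.
#' @param epsilon small positive regularizer added to every kernel value
#'   before exponentiation, so that `K(u,v) = 0` with `gamma < 0` cannot
#'   produce an infinite probability. Default `1e-6`.
#' @param M target total number of edges (seed edges included).
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(eta, gamma = 0, epsilon = 1e-6, M) {
  stopifnot(is.numeric(eta), length(eta) == 1, is.finite(eta),
            is.numeric(gamma), length(gamma) == 1, is.finite(gamma))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("epsilon must be a positive number")
  if (!is.numeric(M) || length(M) != 1 || M != round(M) || M < 0)
    stop("M must be a non-negative integer")
  structure(list(eta = eta, gamma = gamma, epsilon = epsilon, M = as.integer(M)),
            class = "generative_params")
}

# distance factor: E^eta (power law) or exp(eta * E); diagonal zeroed
distance_term <- function(distances, eta, geometric_kernel) {
  dt <- switch(geometric_kernel,
               powerlaw = distances^eta,
               exponential = exp(eta * distances),
               stop("geometric_kernel must be 'powerlaw' or 'exponential'"))
  diag(dt) <- 0
  dt
}

#' Relative connection-formation probabilities
#'
#' Evaluates the growth model's (unnormalized) relative probability
#' `P(u,v) = E(u,v)^eta * (K(u,v) + eps)^gamma` for every node pair, with
#' `exp(eta * E(u,v))` replacing the power law under the exponential
#' geometric kernel. Pairs that are already connected, and the diagonal,
#' have probability exactly zero: once an edge is placed it can never be
#' selected again.
#'
#' @param distances pairwise Euclidean distance matrix.
#' @param kernel kernel matrix from [wiring_kernel()].
#' @param params a [generative_params()] object.
#' @param adjacency current binary adjacency matrix.
#' @param geometric_kernel `"powerlaw"` (default) or `"exponential"`.
#' @return Matrix of relative probabilities; all entries finite and >= 0.
#' @export
relative_probabilities <- function(distances, kernel, params, adjacency,
                                   geometric_kernel = c("powerlaw", "exponential")) {
  geometric_kernel <- match.arg(geometric_kernel)
  distances <- as.matrix(distances)
  kernel <- as.matrix(kernel)
  adjacency <- graph_adjacency(adjacency)
  if (!all(dim(distances) == dim(adjacency)) ||
      !all(dim(kernel) == dim(adjacency)))
    stop("distances, kernel and adjacency must have identical dimensions")
  P <- distance_term(distances, params$eta, geometric_kernel) *
    (kernel + params$epsilon)^params$gamma
  P[adjacency == 1] <- 0
  diag(P) <- 0
  if (any(!is.finite(P))) {
    bad <- which(!is.finite(P), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("non-finite relative probability for pair (%d, %d): ",
                        "E = %g, K = %g, eta = %g, gamma = %g"),
                 bad[1], bad[2], distances[bad[1], bad[2]],
                 kernel[bad[1], bad[2]], params$eta, params$gamma))
  }
  P
}

#' Grow a synthetic network edge-by-edge
#'
#' Starting from the seed network, adds one edge per step until `M` total
#' edges are present. At each step every currently unconnected pair is a
#' candidate, drawn with probability proportional to
#' `E(u,v)^eta * (K(u,v) + eps)^gamma`; the kernel is updated after every
#' placement, and placed edges are excluded from all later steps. Sampling
#' uses inverse-CDF over the upper triangle in a fixed pair ordering, so a
#' run is reproducible bit-for-bit given `rng_seed`.
#'
#' @param seed_graph a `spatial_graph` holding the seed edges (possibly
#'   edgeless) and node coordinates.
#' @param rule one of [wiring_rule_names()].
#' @param params a [generative_params()] object; `params$M` counts seed
#'   edges. For the geometric rule `gamma` is ignored (treated as 0).
#' @param rng_seed integer seed passed to [set.seed()]; `NULL` continues
#'   the current RNG stream.
#' @param geometric_kernel `"powerlaw"` (default) or `"exponential"`.
#' @param distances optional precomputed distance matrix.
#' @param check_kernel if `TRUE`, replay the trace after growth and verify
#'   at a few checkpoints that the engine's incremental kernel maintenance
#'   matches a from-scratch recomputation (test mode; adds O(n^3) work).
#' @return An object of class `growth_trace`: list with `edges` (matrix of
#'   step, u, v), `graph` (the final `spatial_graph`), `rule`, `params`,
#'   `rng_seed` and `geometric_kernel`.
#' @export
#' @examples
#' cfg <- fixture_config(n = 20, rng_seed = 7)
#' coords <- make_coords(cfg)
#' seed <- make_seed_graph(coords, 3)
#' tr <- grow_network(seed, "matching",
#'                    generative_params(eta = -1, gamma = 0.4, M = 19),
#'                    rng_seed = 1)
#' edge_count(tr$graph)
grow_network <- function(seed_graph, rule, params, rng_seed = NULL,
                         geometric_kernel = c("powerlaw", "exponential"),
                         distances = NULL, check_kernel = FALSE) {
  geometric_kernel <- match.arg(geometric_kernel)
  rule <- match_rule(rule)
  if (!is_spatial_graph(seed_graph))
    stop("seed_graph must be a spatial_graph")
  if (!inherits(params, "generative_params"))
    stop("params must be created with generative_params()")
  n <- seed_graph$n
  m0 <- edge_count(seed_graph)
  if (params$M < m0)
    stop("M (", params$M, ") is below the seed edge count (", m0, ")")
  if (params$M > n * (n - 1) / 2)
    stop("M exceeds the number of available node pairs")
  if (is.null(distances)) distances <- euclidean_distances(seed_graph$coords)
  gamma <- if (rule == "geometric") 0 else params$gamma
  dterm <- distance_term(distances, params$eta, geometric_kernel)

  A <- seed_graph$adjacency
  storage.mode(A) <- "integer"
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- .grow_cpp(A, dterm, gamma, params$epsilon, params$M, rule)

  edges <- res$edges
  steps <- nrow(edges)
  trace <- structure(
    list(edges = cbind(step = seq_len(steps), u = edges[, 1], v = edges[, 2]),
         graph = spatial_graph(res$adjacency, seed_graph$coords,
                               seed_graph$labels),
         rule = rule, params = params, rng_seed = rng_seed,
         geometric_kernel = geometric_kernel),
    class = "growth_trace")
  if (isTRUE(check_kernel)) verify_trace_kernel(seed_graph, trace)
  trace
}

#' @export
print.growth_trace <- function(x, ...) {
  cat(sprintf("<growth_trace> rule %s, %d placed edges -> %d total, eta = %g, gamma = %g\n",
              x$rule, nrow(x$edges), edge_count(x$graph),
              x$params$eta, x$params$gamma))
  invisible(x)
}

# Replay a trace, checking the engine's implicit incremental kernel against
# wiring_kernel() at a handful of evenly spaced checkpoints.
verify_trace_kernel <- function(seed_graph, trace) {
  A <- seed_graph$adjacency
  K <- wiring_kernel(A, trace$rule)
  steps <- nrow(trace$edges)
  checkpoints <- unique(round(seq(1, steps, length.out = min(steps, 4L))))
  for (s in seq_len(steps)) {
    e <- trace$edges[s, c("u", "v")]
    K <- update_wiring_kernel(A, trace$rule, K, e)
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
    if (s %in% checkpoints) {
      ref <- wiring_kernel(A, trace$rule)
      if (!isTRUE(all.equal(K, ref, tolerance = 0)))
        stop("incremental kernel diverged from recomputation at step ", s)
    }
  }
  invisible(TRUE)
}
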