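with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Global graph-theoretic measures
#'
#' Standard binary undirected summary measures used to cross-validate
#' best-fitting ensembles on dimensions that were not part of the energy
#' function: mean local clustering coefficient `C`, modularity `Q` (from a
#' deterministic greedy modularity maximization), global efficiency,
#' characteristic path length `L`, degree assortativity `R_k` (Pearson
#' degree-degree correlation over edges) and hop-count diameter.
#'
#' Connectomes thresholded at ~10% density can fracture into several
#' components; by default path-based measures average over reachable pairs
#' only. Under `disconnected = "infinite"`, unreachable pairs contribute
#' zero to efficiency and make `L` and the diameter infinite. Degree
#' assortativity is undefined on regular graphs (zero degree variance);
#' it is then reported as 0 with `assortativity_defined = FALSE`.
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @param disconnected `"reachable"` (default) or `"infinite"`.
#' @return A list with elements `clustering`, `modularity`, `efficiency`,
#'   `path_length`, `assortativity`, `diameter`,
#'   `assortativity_defined`.
#' @export
global_measures <- function(graph, disconnected = c("reachable", "infinite")) {
  disconnected <- match.arg(disconnected)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  g <- as_igraph(A)
  C <- if (n > 0) mean(clustering_vector(A)) else NA_real_

  # multi-start modularity maximization: best of several fixed-seed Louvain
  # runs plus deterministic greedy agglomeration; the caller's RNG stream is
  # restored afterwards
  Q <- if (igraph::ecount(g) > 0) {
    with_preserved_rng({
      qs <- vapply(1:5, function(s) {
        set.seed(s)
        igraph::modularity(igraph::cluster_louvain(g))
      }, numeric(1))
      max(qs, igraph::modularity(igraph::cluster_fast_greedy(g)))
    })
  } else NA_real_

  dm <- igraph::distances(g)
  off <- dm[upper.tri(dm)]
  reach <- is.finite(off)
  if (!any(reach)) {
    eff <- 0; L <- NA_real_; diam <- NA_real_
  } else if (disconnected == "reachable") {
    eff <- mean(1 / off[reach])
    L <- mean(off[reach])
    diam <- max(off[reach])
  } else {
    eff <- sum(1 / off[reach]) / length(off)
    L <- if (all(reach)) mean(off) else Inf
    diam <- if (all(reach)) max(off) else Inf
  }

  Rk <- igraph::assortativity_degree(g)
  Rk_def <- is.finite(Rk)
  if (!Rk_def) Rk <- 0

  list(clustering = C, modularity = Q, efficiency = eff, path_length = L,
       assortativity = Rk, diameter = diam, assortativity_defined = Rk_def)
}

#' Pooled degree-degree-length connection records
#'
#' One record per edge: the two endpoint degrees ordered so `k1 <= k2`,
#' and the edge's Euclidean length. These records feed the 3-D cumulative
#' distribution used to test whether a model reproduces the propensity of
#' high-degree nodes to be linked by long connections.
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @param distances optional distance matrix (computed from coordinates
#'   when absent).
#' @return Data frame with columns `k1`, `k2`, `length`.
#' @export
degree_length_records <- function(graph, distances = NULL) {
  A <- graph_adjacency(graph)
  if (is.null(distances)) {
    if (!is_spatial_graph(graph))
      stop("distances must be supplied when graph has no coordinates")
    distances <- euclidean_distances(graph$coords)
  }
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  k <- rowSums(A)
  ku <- k[idx[, 1]]
  kv <- k[idx[, 2]]
  data.frame(k1 = pmin(ku, kv), k2 = pmax(ku, kv),
             length = distances[idx])
}

orthant_cdf <- function(records, pts) {
  vapply(seq_len(nrow(pts)), function(i) {
    mean(records$k1 <= pts$k1[i] & records$k2 <= pts$k2[i] &
           records$length <= pts$length[i])
  }, numeric(1))
}

#' KS statistic between two 3-D connection distributions
#'
#' The empirical 3-D CDF `F(ka, kb, e)` of a record set is the fraction of
#' records componentwise below the evaluation point. The statistic is the
#' maximum absolute difference between the two CDFs over the union of both
#' record sets' points (a fixed convention: the multivariate KS statistic
#' has no canonical definition, and the orthant-CDF supremum over observed
#' points is attained on that union).
#'
#' @param observed_records,synthetic_records non-empty data frames from
#'   [degree_length_records()] (columns `k1 <= k2`, `length`).
#' @return The 3-D KS statistic, in `[0, 1]`.
#' @export
degree_length_ks <- function(observed_records, synthetic_records) {
  if (nrow(observed_records) == 0 || nrow(synthetic_records) == 0)
    stop("both record sets must be non-empty")
  pts <- rbind(observed_records[c("k1", "k2", "length")],
               synthetic_records[c("k1", "k2", "length")])
  max(abs(orthant_cdf(observed_records, pts) -
            orthant_cdf(synthetic_records, pts)))
}

#' Per-node z-scores against a synthetic ensemble
#'
#' Standardizes each node's observed degree and clustering coefficient
#' against the per-node distributions of an ensemble of synthetic networks
#' (typically the top-1% lowest-energy networks). Larger absolute scores
#' indicate nodes whose local statistics the model fails to reproduce.
#' Nodes where the ensemble standard deviation is zero are flagged
#' undefined (`NA` z-score).
#'
#' @param observed a `spatial_graph`.
#' @param ensemble list of at least two `spatial_graph`s on the same node
#'   set.
#' @return Data frame with columns `node`, `degree_z`, `clustering_z`,
#'   `degree_defined`, `clustering_defined`.
#' @export
node_zscores <- function(observed, ensemble) {
  if (length(ensemble) < 2) stop("ensemble must contain at least two networks")
  n <- observed$n
  if (any(vapply(ensemble, function(g) graph_nodes(g) != n, logical(1))))
    stop("all ensemble networks must share the observed node count")
  deg <- vapply(ensemble, function(g) rowSums(graph_adjacency(g)), numeric(n))
  clu <- vapply(ensemble, function(g) clustering_vector(graph_adjacency(g)),
                numeric(n))
  zcol <- function(obs, mat) {
    mu <- rowMeans(mat)
    s <- apply(mat, 1, stats::sd)
    # degenerate ensemble: flag it, but an exact match is still a zero score
    z <- ifelse(s > 0, (obs - mu) / s, ifelse(obs == mu, 0, NA_real_))
    list(z = z, defined = s > 0)
  }
  zk <- zcol(rowSums(observed$adjacency), deg)
  zc <- zcol(clustering_vector(observed$adjacency), clu)
  data.frame(node = seq_len(n),
             degree_z = zk$z, clustering_z = zc$z,
             degree_defined = zk$defined, clustering_defined = zc$defined)
}

graph_nodes <- function(graph) {
  if (is_spatial_graph(graph)) graph$n else nrow(as.matrix(graph))
}

#' Density-preserving uniform null ensemble
#'
#' Baseline generative model in which connections are formed with uniform
#' probability: each network is the seed plus `M - m_seed` pairs drawn
#' uniformly without replacement from the currently unconnected pairs.
#' Only the connection density (and the seed) is preserved — not the
#' degree sequence.
#'
#' @param n node count.
#' @param M total edges per network.
#' @param count number of networks to draw.
#' @param seed_graph optional `spatial_graph` seed; its edges appear in
#'   every draw.
#' @param coords node coordinates (taken from `seed_graph` when absent).
#' @param rng_seed integer seed.
#' @return List of `count` `spatial_graph`s, each with exactly `M` edges.
#' @export
uniform_null_ensemble <- function(n, M, count, seed_graph = NULL,
                                  coords = NULL, rng_seed = NULL) {
  if (M > n * (n - 1) / 2) stop("M exceeds the number of available node pairs")
  if (is.null(coords)) {
    if (is.null(seed_graph))
      stop("supply coords or a seed_graph carrying coordinates")
    coords <- seed_graph$coords
  }
  A0 <- if (is.null(seed_graph)) matrix(0, n, n) else seed_graph$adjacency
  m0 <- sum(A0) / 2
  if (M < m0) stop("M is below the seed edge count")
  free <- which(upper.tri(A0) & A0 == 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  lapply(seq_len(count), function(i) {
    A <- A0
    picked <- sample(free, M - m0)
    A[picked] <- 1
    A <- A + t(A) - A0 # picked entries live in the upper triangle only
    A[A > 1] <- 1
    spatial_graph(A, coords)
  })
}

#' Standardize an energy record against a null ensemble
#'
#' Expresses each KS component and the energy as a z-score relative to the
#' distribution of the same quantity over a set of null records (for
#' example, energies of [uniform_null_ensemble()] networks). Used to
#' compare fits across networks of different densities. Components with
#' zero null variance are flagged undefined.
#'
#' @param record an `energy_record`.
#' @param null_records list of at least two `energy_record`s.
#' @return An object of class `energy_zscores`: list with `KS_k`, `KS_c`,
#'   `KS_b`, `KS_e`, `energy` (z-scores, `NA` when undefined) and a
#'   logical `defined` vector.
#' @export
zscore_energy <- function(record, null_records) {
  if (length(null_records) < 2)
    stop("need at least two null records")
  fields <- c(energy_component_names, "energy")
  nul <- vapply(null_records,
                function(r) unlist(r[fields]), numeric(length(fields)))
  mu <- rowMeans(nul)
  s <- apply(nul, 1, stats::sd)
  x <- unlist(record[fields])
  z <- ifelse(s > 0, (x - mu) / s, ifelse(x == mu, 0, NA_real_))
  structure(c(as.list(z), list(defined = stats::setNames(s > 0, fields))),
            class = "energy_zscores")
}

#' @export
print.energy_zscores <- function(x, ...) {
  cat(sprintf("<energy_zscores> energy z = %.3f; KS z: k %.3f, c %.3f, b %.3f, e %.3f\n",
              x$energy, x$KS_k, x$KS_c, x$KS_b, x$KS_e))
  invisible(x)
}
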