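#' Names of the supported wiring rules
#'
#' Thirteen rules: the pure geometric rule (`K(u,v) = 1`) plus twelve
#' topological kernels built from node degree (`deg-*`), local clustering
#' (`clu-*`), the raw common-neighbour count (`neighbors`) and the matching
#' index (`matching`). The `*-avg`, `*-diff`, `*-max`, `*-min` and `*-prod`
#' variants combine the two endpoint values by arithmetic mean, absolute
#' difference, maximum, minimum and product respectively.
#'
#' @return Character vector of rule names.
#' @export
wiring_rule_names <- function() {
  c("geometric",
    "clu-avg", "clu-diff", "clu-max", "clu-min", "clu-prod",
    "deg-avg", "deg-diff", "deg-max", "deg-min", "deg-prod",
    "neighbors", "matching")
}

match_rule <- function(rule) {
  rules <- wiring_rule_names()
  if (length(rule) != 1 || !rule %in% rules)
    stop("unknown wiring rule '", paste(rule, collapse = ","),
         "'; valid rules are: ", paste(rules, collapse = ", "))
  rule
}

# combine endpoint values x into an n x n pairwise kernel
pairwise_combine <- function(x, op) {
  switch(op,
         avg  = outer(x, x, `+`) / 2,
         diff = abs(outer(x, x, `-`)),
         max  = outer(x, x, pmax),
         min  = outer(x, x, pmin),
         prod = outer(x, x))
}

#' Topological kernel K(u,v) of a wiring rule
#'
#' Evaluates the kernel of one of the thirteen wiring rules on the current
#' graph. The kernel enters the growth model as
#' `P(u,v) = E(u,v)^eta * (K(u,v) + eps)^gamma`; the geometric rule has
#' `K(u,v) = 1` everywhere off the diagonal, so distance alone drives it.
#' The diagonal is stored as zero by convention and never used (self-loops
#' are forbidden upstream).
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @param rule one of [wiring_rule_names()].
#' @return Symmetric numeric `n x n` kernel matrix with zero diagonal.
#' @export
#' @examples
#' A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
#' wiring_kernel(A, "deg-prod")
wiring_kernel <- function(graph, rule) {
  rule <- match_rule(rule)
  A <- graph_adjacency(graph)
  n <- nrow(A)
  K <- if (rule == "geometric") {
    matrix(1, n, n)
  } else if (rule == "neighbors") {
    A %*% A
  } else if (rule == "matching") {
    matching_kernel(A)
  } else {
    parts <- strsplit(rule, "-", fixed = TRUE)[[1]]
    x <- if (parts[1] == "deg") rowSums(A) else clustering_vector(A)
    pairwise_combine(x, parts[2])
  }
  diag(K) <- 0
  K
}

matching_kernel <- function(A) {
  k <- rowSums(A)
  cn <- A %*% A                       # common-neighbour counts
  uni <- outer(k, k, `+`) - 2 * A - cn # |reduced union|
  M <- matrix(0, nrow(A), ncol(A))
  pos <- uni > 0
  M[pos] <- cn[pos] / uni[pos]
  M
}

#' Matching index of all node pairs
#'
#' Normalized overlap of two nodes' neighbourhoods after excluding the pair
#' itself: with `G_u\\v` the neighbours of `u` other than `v`,
#' `M(u,v) = |G_u\\v intersect G_v\\u| / |G_u\\v union G_v\\u|`,
#' and 0 when the union is empty. Nodes with identical non-empty reduced
#' neighbourhoods score 1; nodes sharing no neighbour score 0. This is the
#' homophily kernel of the best-performing wiring rule.
#'
#' @inheritParams wiring_kernel
#' @return Symmetric matrix of matching indices in `[0, 1]`, zero diagonal.
#' @export
matching_index <- function(graph) {
  A <- graph_adjacency(graph)
  M <- matching_kernel(A)
  diag(M) <- 0
  M
}

#' Incrementally update a kernel after one edge insertion
#'
#' Given the kernel of `graph` under `rule` and a new edge, returns the
#' kernel of the graph with that edge added, recomputing only the rows and
#' columns an insertion can affect (endpoint rows for degree-, neighbour-
#' and matching-based rules; endpoints plus their common neighbours for
#' clustering-based rules; nothing for the geometric rule). Incremental
#' updates and from-scratch recomputation agree exactly at every step of a
#' growth trajectory.
#'
#' @param graph the `spatial_graph` (or adjacency matrix) *before* the
#'   insertion.
#' @param rule one of [wiring_rule_names()].
#' @param kernel kernel of `graph` under `rule`.
#' @param edge integer vector `c(u, v)` of 1-based node indices; the edge
#'   must not already be present.
#' @return The updated kernel matrix.
#' @export
update_wiring_kernel <- function(graph, rule, kernel, edge) {
  rule <- match_rule(rule)
  A <- graph_adjacency(graph)
  u <- edge[1]
  v <- edge[2]
  if (u == v) stop("self-loops are not allowed")
  if (A[u, v] == 1)
    stop("edge {", u, ",", v, "} is already present")
  if (rule == "geometric") return(kernel)

  A2 <- A
  A2[u, v] <- A2[v, u] <- 1
  S <- if (startsWith(rule, "clu-")) {
    unique(c(u, v, which(A[, u] == 1 & A[, v] == 1)))
  } else {
    c(u, v)
  }

  K <- kernel
  rows <- if (rule == "neighbors") {
    A2[S, , drop = FALSE] %*% A2
  } else if (rule == "matching") {
    k2 <- rowSums(A2)
    cnS <- A2[S, , drop = FALSE] %*% A2
    uniS <- outer(k2[S], k2, `+`) - 2 * A2[S, , drop = FALSE] - cnS
    MS <- matrix(0, length(S), ncol(A2))
    pos <- uniS > 0
    MS[pos] <- cnS[pos] / uniS[pos]
    MS
  } else {
    parts <- strsplit(rule, "-", fixed = TRUE)[[1]]
    x2 <- if (parts[1] == "deg") rowSums(A2) else clustering_vector(A2)
    switch(parts[2],
           avg  = outer(x2[S], x2, `+`) / 2,
           diff = abs(outer(x2[S], x2, `-`)),
           max  = outer(x2[S], x2, pmax),
           min  = outer(x2[S], x2, pmin),
           prod = outer(x2[S], x2))
  }
  K[S, ] <- rows
  K[, S] <- t(rows)
  diag(K) <- 0
  K
}
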