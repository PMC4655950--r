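#' Construct a spatial graph
#'
#' Bundles a binary undirected adjacency matrix with 3-D node centroid
#' coordinates (mm). This is the substrate every other function in the
#' package operates on: networks are grown on it, scored on it, and all
#' node- and edge-level statistics are computed from it.
#'
#' @param adjacency square symmetric matrix with entries in \{0, 1\} and a
#'   zero diagonal.
#' @param coords numeric matrix with one row per node and three columns
#'   (x, y, z, in mm); all values must be finite.
#' @param labels optional character vector of node labels; defaults to the
#'   row names of `coords` or `"1"..."n"`.
#' @return An object of class `spatial_graph`: a list with elements `n`,
#'   `adjacency`, `coords` and `labels`.
#' @export
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
#' xyz <- cbind(c(0, 3, 0), c(0, 4, 8), 0)
#' g <- spatial_graph(A, xyz)
#' edge_count(g)
spatial_graph <- function(adjacency, coords, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  coords <- as.matrix(coords)
  storage.mode(adjacency) <- "double"
  storage.mode(coords) <- "double"
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop("adjacency must be a square matrix")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(adjacency != t(adjacency)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal (no self-loops)")
  if (nrow(coords) != n)
    stop("coords must have exactly one row per node (", n, " expected, got ",
         nrow(coords), ")")
  if (ncol(coords) != 3)
    stop("coords must have three columns (x, y, z)")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  if (is.null(labels)) labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dimnames(adjacency) <- NULL
  dimnames(coords) <- NULL
  structure(list(n = n, adjacency = adjacency, coords = coords,
                 labels = as.character(labels)),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges, density %.3f\n",
              x$n, edge_count(x),
              if (x$n > 1) edge_count(x) / (x$n * (x$n - 1) / 2) else NA_real_))
  invisible(x)
}

#' @rdname spatial_graph
#' @param x object to test.
#' @export
is_spatial_graph <- function(x) inherits(x, "spatial_graph")

#' Number of undirected edges in a graph
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @return Integer edge count.
#' @export
edge_count <- function(graph) {
  A <- graph_adjacency(graph)
  sum(A) / 2
}

# Accept either a spatial_graph or a bare adjacency matrix.
graph_adjacency <- function(graph) {
  if (is_spatial_graph(graph)) graph$adjacency else as.matrix(graph)
}

#' Pairwise Euclidean distance matrix
#'
#' Distances between node centroids in mm. Coincident nodes are rejected:
#' a zero off-diagonal distance makes the power-law distance factor of the
#' growth model undefined for negative exponents.
#'
#' @param coords numeric matrix of node coordinates (rows = nodes), or a
#'   `spatial_graph`.
#' @return Symmetric matrix of pairwise Euclidean distances with zero
#'   diagonal.
#' @export
#' @examples
#' euclidean_distances(rbind(c(0, 0, 0), c(3, 4, 0)))
euclidean_distances <- function(coords) {
  if (is_spatial_graph(coords)) coords <- coords$coords
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least two nodes")
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- NULL
  zero <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop(sprintf("nodes %d and %d have identical coordinates (zero distance)",
                 zero[1, 1], zero[1, 2]))
  D
}

# local clustering coefficient vector, with c := 0 for degree < 2
clustering_vector <- function(A) {
  k <- rowSums(A)
  tri <- rowSums(A * (A %*% A)) / 2
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

#' Node-level statistics
#'
#' Degree, local (Watts-Strogatz) clustering coefficient and unweighted
#' shortest-path betweenness centrality for every node. Betweenness is the
#' raw (unnormalized) count with endpoints excluded and each unordered pair
#' counted once; nodes of degree below two have clustering zero; unreachable
#' pairs contribute nothing. The same conventions are applied to observed
#' and synthetic networks, which is all the energy comparison requires.
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @return A data frame with columns `degree`, `clustering`, `betweenness`,
#'   one row per node.
#' @export
node_statistics <- function(graph) {
  A <- graph_adjacency(graph)
  n <- nrow(A)
  if (n == 0)
    return(data.frame(degree = numeric(0), clustering = numeric(0),
                      betweenness = numeric(0)))
  Ai <- A
  storage.mode(Ai) <- "integer"
  data.frame(degree = rowSums(A),
             clustering = clustering_vector(A),
             betweenness = .betweenness_cpp(Ai))
}

#' Edge length sample
#'
#' Euclidean length (mm) of every existing edge, each undirected edge
#' counted once.
#'
#' @param graph a `spatial_graph` or binary adjacency matrix.
#' @param distances optional precomputed distance matrix; computed from the
#'   graph's coordinates when absent.
#' @return Numeric vector with one length per edge.
#' @export
edge_lengths <- function(graph, distances = NULL) {
  A <- graph_adjacency(graph)
  if (is.null(distances)) {
    if (!is_spatial_graph(graph))
      stop("distances must be supplied when graph has no coordinates")
    distances <- euclidean_distances(graph$coords)
  }
  distances <- as.matrix(distances)
  if (!all(dim(distances) == dim(A)))
    stop("distance matrix dimensions do not match the adjacency")
  distances[upper.tri(A) & A == 1]
}

# internal: igraph view of a graph (evaluation-module measures)
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph_adjacency(graph),
                                      mode = "undirected", diag = FALSE)
}
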