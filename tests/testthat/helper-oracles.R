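# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): scalar loops, Floyd-Warshall path counting,
# literal set arithmetic. Slow but unambiguous on small graphs.

oracle_distances <- function(coords) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  D
}

# Floyd-Warshall shortest-path lengths and shortest-path counts.
# At stage k, sigma counts paths whose intermediate vertices are all <= k;
# each shortest path is counted exactly once, at its largest intermediate.
oracle_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sig <- matrix(0, n, n)
  d[A == 1] <- 1
  sig[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || k == i || k == j) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) {
      d[i, j] <- alt
      sig[i, j] <- sig[i, k] * sig[k, j]
    } else if (is.finite(alt) && alt == d[i, j]) {
      sig[i, j] <- sig[i, j] + sig[i, k] * sig[k, j]
    }
  }
  list(d = d, sigma = sig)
}

# unnormalized betweenness, endpoints excluded, each unordered pair once
oracle_betweenness <- function(A) {
  n <- nrow(A)
  fw <- oracle_paths(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(fw$d[s, t])) next
    for (w in seq_len(n)) {
      if (w == s || w == t) next
      if (is.finite(fw$d[s, w]) && is.finite(fw$d[w, t]) &&
          fw$d[s, w] + fw$d[w, t] == fw$d[s, t])
        b[w] <- b[w] + fw$sigma[s, w] * fw$sigma[w, t] / fw$sigma[s, t]
    }
  }
  b
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(A[u, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in nb) for (j in nb) if (i < j && A[i, j] == 1) tri <- tri + 1
    cc[u] <- 2 * tri / (k * (k - 1))
  }
  cc
}

oracle_ks <- function(a, b) {
  best <- 0
  for (x in c(a, b)) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    best <- max(best, abs(fa - fb))
  }
  best
}

# literal per-pair evaluation of each wiring-rule formula
oracle_kernel <- function(A, rule) {
  n <- nrow(A)
  k <- rowSums(A)
  cc <- oracle_clustering(A)
  K <- matrix(0, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    K[u, v] <- switch(rule,
      "geometric" = 1,
      "deg-avg"  = (k[u] + k[v]) / 2,
      "deg-diff" = abs(k[u] - k[v]),
      "deg-max"  = max(k[u], k[v]),
      "deg-min"  = min(k[u], k[v]),
      "deg-prod" = k[u] * k[v],
      "clu-avg"  = (cc[u] + cc[v]) / 2,
      "clu-diff" = abs(cc[u] - cc[v]),
      "clu-max"  = max(cc[u], cc[v]),
      "clu-min"  = min(cc[u], cc[v]),
      "clu-prod" = cc[u] * cc[v],
      "neighbors" = sum(A[u, ] * A[v, ]),
      "matching" = {
        Nu <- setdiff(which(A[u, ] == 1), v)
        Nv <- setdiff(which(A[v, ] == 1), u)
        un <- union(Nu, Nv)
        if (length(un) == 0) 0 else length(intersect(Nu, Nv)) / length(un)
      })
  }
  K
}

# 3-D orthant-CDF KS by explicit double loop
oracle_degree_length_ks <- function(ro, rs) {
  pts <- rbind(ro, rs)
  best <- 0
  for (i in seq_len(nrow(pts))) {
    fo <- mean(ro$k1 <= pts$k1[i] & ro$k2 <= pts$k2[i] &
                 ro$length <= pts$length[i])
    fs <- mean(rs$k1 <= pts$k1[i] & rs$k2 <= pts$k2[i] &
                 rs$length <= pts$length[i])
    best <- max(best, abs(fo - fs))
  }
  best
}

# seeded Erdos-Renyi-style spatial graph for parameterized cases
random_spatial_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  coords <- matrix(stats::runif(3 * n, 0, 50), n, 3)
  spatial_graph(A, coords)
}

# small canonical graphs
path_graph3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  spatial_graph(A, cbind(c(0, 1, 2), 0, 0))
}

two_triangles <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  spatial_graph(A, cbind(c(0, 1, 0.5, 10, 11, 10.5), c(0, 0, 1, 0, 0, 1), 0))
}

# independent nearest-generator check (scalar, lowest index wins ties)
nearest_cell_of <- function(gens, pt) {
  d2 <- colSums((t(gens) - pt)^2)
  which.min(d2)
}

uniform_box_draw <- function(box) {
  c(stats::runif(1, box$eta[1], box$eta[2]),
    stats::runif(1, box$gamma[1], box$gamma[2]))
}

# Coordinates for the greedy-growth check: searched over fixed seeds until,
# at every one of `steps` greedy closest-pair deletions, the shortest
# remaining distance is at least `margin` times shorter than the runner-up.
# The certification is part of the construction, so the returned fixture is
# deterministic and self-validating.
greedy_test_coords <- function(n = 6, steps = 9, margin = 1.15) {
  for (seed in 1:500) {
    set.seed(seed)
    coords <- matrix(stats::runif(3 * n, 0, 4), n, 3)
    D <- oracle_distances(coords)
    Dm <- D
    diag(Dm) <- Inf
    ok <- TRUE
    for (s in seq_len(steps)) {
      vals <- sort(Dm[is.finite(Dm)])
      if (length(vals) < 4 || vals[3] / vals[1] < margin) { ok <- FALSE; break }
      pick <- which(Dm == vals[1], arr.ind = TRUE)[1, ]
      Dm[pick[1], pick[2]] <- Dm[pick[2], pick[1]] <- Inf
    }
    if (ok) return(coords)
  }
  stop("no suitable greedy-test configuration found")
}
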