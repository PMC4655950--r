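test_that("relative probabilities follow the distance-kernel product law", {
  # 4-node toy, deg-prod, eta = -1, gamma = 1: entries hand-computed
  coords <- cbind(c(0, 3, 0, 6), c(0, 4, 8, 0), 0)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  D <- euclidean_distances(coords)
  k <- c(1, 2, 1, 0)
  p <- generative_params(eta = -1, gamma = 1, M = 3)
  P <- relative_probabilities(D, wiring_kernel(A, "deg-prod"), p, A)
  for (u in 1:3) for (v in (u + 1):4) {
    want <- if (A[u, v] == 1) 0 else (1 / D[u, v]) * (k[u] * k[v] + 1e-6)
    expect_equal(P[u, v], want, info = paste(u, v))
    expect_equal(P[v, u], P[u, v])
  }
  expect_equal(diag(P), rep(0, 4))
})

test_that("eta = gamma = 0 makes all unconnected pairs equiprobable", {
  g <- random_spatial_graph(9, p = 0.25, seed = 3)
  D <- euclidean_distances(g$coords)
  p <- generative_params(0, 0, M = 10)
  P <- relative_probabilities(D, wiring_kernel(g, "matching"), p, g$adjacency)
  off <- P[upper.tri(P)]
  free <- g$adjacency[upper.tri(g$adjacency)] == 0
  expect_true(all(off[free] == off[free][1]))
  expect_true(all(off[!free] == 0))
})

test_that("exponential geometric kernel replaces the power law", {
  g <- random_spatial_graph(6, p = 0.3, seed = 4)
  D <- euclidean_distances(g$coords)
  p <- generative_params(-0.1, 0.5, M = 8)
  K <- wiring_kernel(g, "deg-avg")
  P <- relative_probabilities(D, K, p, g$adjacency, "exponential")
  free <- which(upper.tri(D) & g$adjacency == 0, arr.ind = TRUE)
  u <- free[1, 1]; v <- free[1, 2]
  expect_equal(P[u, v], exp(-0.1 * D[u, v]) * (K[u, v] + 1e-6)^0.5)
})

test_that("growth honours its contract: edge budget, seed inclusion, reproducibility", {
  cfg <- fixture_config(n = 25, rng_seed = 5)
  coords <- make_coords(cfg)
  seed <- make_seed_graph(coords, 5)
  p <- generative_params(-1, 0.4, M = 30)

  tr <- grow_network(seed, "matching", p, rng_seed = 1)
  expect_equal(edge_count(tr$graph), 30)
  expect_true(all(tr$graph$adjacency[seed$adjacency == 1] == 1))
  expect_equal(nrow(tr$edges), 25)

  tr2 <- grow_network(seed, "matching", p, rng_seed = 1)
  expect_identical(tr$edges, tr2$edges)
  expect_identical(tr$graph$adjacency, tr2$graph$adjacency)

  # M equal to the seed edge count: nothing to place
  tr0 <- grow_network(seed, "matching", generative_params(-1, 0.4, M = 5))
  expect_equal(nrow(tr0$edges), 0)
  expect_identical(tr0$graph$adjacency, seed$adjacency)

  expect_error(grow_network(seed, "matching", generative_params(-1, 0.4, M = 2)),
               "below the seed")
  expect_error(grow_network(seed, "matching", generative_params(-1, 0.4, M = 400)),
               "exceeds")
})

test_that("a strongly negative eta reduces to greedy closest-pair growth", {
  # coordinates constructed (and certified by the helper) so that at every
  # greedy step the closest unconnected pair is at least 15% shorter than
  # the runner-up; at eta = -300 that margin outweighs the runner-up by
  # a factor >= 1.08^300 ~ 1e10, making the draw effectively deterministic
  coords <- greedy_test_coords(n = 6, steps = 6, margin = 1.08)
  D <- euclidean_distances(coords)
  n <- nrow(coords)
  empty <- spatial_graph(matrix(0, n, n), coords)
  tr <- grow_network(empty, "geometric", generative_params(-300, 0, M = 6),
                     rng_seed = 8)

  greedy <- matrix(0, n, n)
  for (s in 1:6) {
    Dm <- D
    Dm[greedy == 1] <- Inf
    diag(Dm) <- Inf
    pick <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
    greedy[pick[1], pick[2]] <- greedy[pick[2], pick[1]] <- 1
  }
  expect_identical(tr$graph$adjacency, greedy)
})

test_that("mean edge length decreases stochastically with the distance penalty", {
  cfg <- fixture_config(n = 30, rng_seed = 2)
  coords <- make_coords(cfg)
  empty <- spatial_graph(matrix(0, 30, 30), coords)
  D <- euclidean_distances(coords)
  mean_len <- function(eta, seeds) {
    vapply(seeds, function(s) {
      tr <- grow_network(empty, "geometric", generative_params(eta, 0, M = 44),
                         rng_seed = s, distances = D)
      mean(edge_lengths(tr$graph, D))
    }, numeric(1))
  }
  flat <- mean_len(0, 1:30)
  penal <- mean_len(-4, 1:30)
  expect_lt(stats::wilcox.test(penal, flat, alternative = "less")$p.value, 1e-3)
})

test_that("the engine's incremental kernels survive a replay audit", {
  cfg <- fixture_config(n = 20, rng_seed = 7)
  seed <- make_seed_graph(make_coords(cfg), 4)
  for (rule in c("matching", "clu-avg", "deg-prod", "neighbors"))
    expect_no_error(grow_network(seed, rule, generative_params(-1, 0.3, M = 19),
                                 rng_seed = 2, check_kernel = TRUE))
})

test_that("generative parameter validation rejects degenerate inputs", {
  expect_error(generative_params(-1, 0.4, epsilon = 0, M = 10), "positive")
  expect_error(generative_params(-1, 0.4, M = 2.5), "integer")
  expect_error(grow_network(path_graph3(), "not-a-rule",
                            generative_params(-1, 0, M = 3)), "valid rules")
})
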