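test_that("global measures match analytic values on canonical graphs", {
  K5 <- spatial_graph(matrix(1, 5, 5) - diag(5),
                      cbind(rnorm(5), rnorm(5), rnorm(5)))
  m <- global_measures(K5)
  expect_equal(m$clustering, 1)
  expect_equal(m$path_length, 1)
  expect_equal(m$efficiency, 1)
  expect_equal(m$diameter, 1)

  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  g <- spatial_graph(ring, cbind(cos(1:6), sin(1:6), 0))
  m <- global_measures(g)
  expect_equal(m$clustering, 0)
  expect_equal(m$path_length, 1.8) # 6 pairs at 1, 6 at 2, 3 at 3 over 15 pairs
  expect_equal(m$diameter, 3)
  # rings are regular: degree assortativity undefined, flagged and zeroed
  expect_false(m$assortativity_defined)
  expect_equal(m$assortativity, 0)
})

test_that("path measures agree with a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:6) {
    g <- random_spatial_graph(12, p = 0.25, seed = 60 + seed)
    m <- global_measures(g)
    d <- oracle_paths(g$adjacency)$d
    off <- d[upper.tri(d)]
    reach <- is.finite(off)
    expect_equal(m$path_length, mean(off[reach]))
    expect_equal(m$efficiency, mean(1 / off[reach]))
    expect_equal(m$diameter, max(off[reach]))
    # Pearson degree-degree correlation over directed edge stubs
    k <- rowSums(g$adjacency)
    idx <- which(g$adjacency == 1, arr.ind = TRUE)
    want <- suppressWarnings(stats::cor(k[idx[, 1]], k[idx[, 2]]))
    if (is.finite(want)) expect_equal(m$assortativity, want, tolerance = 1e-12)
  }
})

test_that("disconnected graphs support both path conventions", {
  g <- two_triangles()
  m <- global_measures(g, disconnected = "reachable")
  expect_equal(m$path_length, 1)
  expect_equal(m$diameter, 1)
  m2 <- global_measures(g, disconnected = "infinite")
  expect_equal(m2$path_length, Inf)
  expect_equal(m2$efficiency, 6 / 15) # 6 reachable of 15 pairs, all at 1 hop
})

test_that("modularity is competitive with an independent heuristic", {
  for (seed in 1:10) {
    g <- random_spatial_graph(20, p = 0.2, seed = 70 + seed)
    if (edge_count(g) == 0) next
    q <- global_measures(g)$modularity
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
    set.seed(99)
    q_ref <- igraph::modularity(igraph::cluster_louvain(ig))
    expect_gte(q, q_ref - 0.01)
    expect_lte(q, 1)
  }
  # the internal seeding must not disturb the caller's RNG stream
  g <- random_spatial_graph(10, seed = 1)
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(global_measures(g))
  expect_identical(runif(3), before)
})

test_that("3-D degree-length KS matches its brute-force oracle", {
  g1 <- random_spatial_graph(14, p = 0.35, seed = 81)
  g2 <- spatial_graph(random_spatial_graph(14, p = 0.25, seed = 82)$adjacency,
                      g1$coords)
  r1 <- degree_length_records(g1)
  r2 <- degree_length_records(g2)
  expect_true(all(r1$k1 <= r1$k2))
  expect_equal(degree_length_ks(r1, r2), oracle_degree_length_ks(r1, r2),
               tolerance = 1e-12)
  expect_equal(degree_length_ks(r2, r1), degree_length_ks(r1, r2))
  expect_equal(degree_length_ks(r1, r1), 0)
  # records in disjoint orthants are maximally discrepant
  a <- data.frame(k1 = 1, k2 = 2, length = 10)
  b <- data.frame(k1 = 5, k2 = 6, length = 90)
  expect_equal(degree_length_ks(a, b), 1)
  expect_error(degree_length_ks(a[0, ], b), "non-empty")
})

test_that("node z-scores standardize against the ensemble, flagging zero spread", {
  obs <- random_spatial_graph(10, p = 0.4, seed = 91)
  ens <- lapply(92:111, function(s)
    spatial_graph(random_spatial_graph(10, p = 0.4, seed = s)$adjacency,
                  obs$coords))
  z <- node_zscores(obs, ens)
  # two-pass oracle
  degm <- sapply(ens, function(g) rowSums(g$adjacency))
  mu <- apply(degm, 1, mean)
  s <- apply(degm, 1, sd)
  ok <- s > 0
  expect_equal(z$degree_z[ok], ((rowSums(obs$adjacency) - mu) / s)[ok],
               tolerance = 1e-12)
  expect_equal(z$degree_defined, ok)

  # observed identical to every ensemble member: zero scores, flagged spread
  same <- list(obs, obs, obs)
  z0 <- node_zscores(obs, same)
  expect_true(all(z0$degree_z == 0) && all(z0$clustering_z == 0))
  expect_true(all(!z0$degree_defined))
  expect_error(node_zscores(obs, same[1]), "at least two")
})

test_that("uniform null ensembles preserve density and the seed", {
  cfg <- fixture_config(n = 20, rng_seed = 12)
  coords <- make_coords(cfg)
  seed <- make_seed_graph(coords, 4)
  expect_length(uniform_null_ensemble(20, 15, 0, seed_graph = seed), 0)
  ens <- uniform_null_ensemble(20, 15, 25, seed_graph = seed, rng_seed = 3)
  for (g in ens) {
    expect_equal(edge_count(g), 15)
    expect_true(all(g$adjacency[seed$adjacency == 1] == 1))
  }
  expect_error(uniform_null_ensemble(5, 100, 1, coords = coords[1:5, ]),
               "exceeds")
})

test_that("energy z-scoring standardizes each component against the nulls", {
  mk <- function(k, c, b, e) connectogen:::new_energy_record(
    c(KS_k = k, KS_c = c, KS_b = b, KS_e = e))
  nulls <- list(mk(0.4, 0.5, 0.6, 0.3), mk(0.6, 0.7, 0.4, 0.5),
                mk(0.5, 0.6, 0.5, 0.4))
  rec <- mk(0.5, 0.6, 0.5, 0.4)
  z <- zscore_energy(rec, nulls)
  km <- c(0.4, 0.6, 0.5)
  expect_equal(z$KS_k, (0.5 - mean(km)) / sd(km), tolerance = 1e-12)
  # a record at the null mean scores zero everywhere
  em <- c(0.6, 0.7, 0.6)
  expect_equal(z$energy, (0.6 - mean(em)) / sd(em), tolerance = 1e-12)
  # one null sd below the mean scores -1
  rec2 <- mk(mean(km) - sd(km), 0.6, 0.5, 0.4)
  expect_equal(zscore_energy(rec2, nulls)$KS_k, -1, tolerance = 1e-12)
  expect_error(zscore_energy(rec, nulls[1]), "at least two")
})
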