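test_that("cell sampling weights are inverse-energy powers of alpha", {
  set.seed(51)
  # energies 0.1 and 0.2 at alpha = 1: weights 10 and 5, probabilities 2/3, 1/3
  draws <- sample_cells(c(0.1, 0.2), alpha = 1, n_draws = 30000)
  expect_equal(mean(draws == 1), 2 / 3, tolerance = 0.02)
  # alpha = 0: uniform over cells
  draws <- sample_cells(c(0.05, 0.4, 0.9), alpha = 0, n_draws = 30000)
  expect_equal(unname(table(draws)) / 30000, rep(1 / 3, 3), tolerance = 0.03,
               ignore_attr = TRUE)
  # single cell: always that cell
  expect_true(all(sample_cells(0.3, alpha = 2, n_draws = 50) == 1))
  expect_error(sample_cells(c(0.1, 0.2), 1, 0), "positive")
  expect_error(sample_cells(c(0.1, 0.2), -1, 5), "non-negative")
})

test_that("points sampled in a cell satisfy the nearest-generator predicate", {
  set.seed(52)
  box <- parameter_box(eta = c(-2, 2), gamma = c(-1, 1))
  gens <- cbind(runif(8, -2, 2), runif(8, -1, 1))
  for (cell in c(1, 4, 8)) {
    pt <- sample_point_in_cell(gens, cell, box)
    expect_equal(nearest_cell_of(gens, pt), cell)
  }
  # a single generator owns the whole box: uniform-in-box sampling
  lone <- matrix(c(0, 0), 1, 2)
  pts <- t(replicate(400, sample_point_in_cell(lone, 1, box)))
  expect_gt(stats::ks.test(pts[, 1], "punif", -2, 2)$p.value, 0.01)
  expect_gt(stats::ks.test(pts[, 2], "punif", -1, 1)$p.value, 0.01)
})

test_that("two generators mirrored about the box centre split draws evenly", {
  set.seed(53)
  box <- parameter_box(eta = c(-1, 1), gamma = c(-1, 1))
  gens <- rbind(c(-0.4, -0.4), c(0.4, 0.4))
  hits <- replicate(4000, nearest_cell_of(gens, uniform_box_draw(box)))
  expect_equal(mean(hits == 1), 0.5, tolerance = 0.03)
})

test_that("select_best returns the stable lowest-energy order statistics", {
  arch <- data.frame(eta = 1:10, gamma = 0,
                     energy = c(0.5, 0.2, 0.9, 0.2, 0.1, 0.7, 0.3, 0.2, 0.8, 0.6))
  expect_equal(nrow(select_best(arch, 1)), 10)
  top <- select_best(arch, 0.3)
  expect_equal(top$energy, c(0.1, 0.2, 0.2))
  expect_equal(top$eta, c(5, 2, 4)) # ties keep insertion order
  expect_lte(max(top$energy), min(arch$energy[-match(top$eta, arch$eta)]))
  expect_equal(nrow(select_best(arch, 0.01)), 1)
  expect_error(select_best(arch[0, ], 0.5), "empty")
  expect_error(select_best(arch, 0), "fraction")
})

test_that("a small fit produces a complete, reproducible archive", {
  cfg <- fixture_config(n = 30, rng_seed = 6)
  obs <- make_observed(cfg)
  seed <- make_seed_graph(make_coords(cfg), cfg$seed_edges)
  box <- parameter_box(eta = c(-4, 1), gamma = c(-1, 1))
  f1 <- fit_generative_model(obs, "matching", box = box, schedule = c(0, 1),
                             n_samp = 15, seed_graph = seed, rng_seed = 9)
  expect_equal(nrow(f1$archive), 30)
  expect_equal(unique(f1$archive$rep), c(1, 2))
  expect_true(all(f1$archive$eta >= -4 & f1$archive$eta <= 1))
  expect_true(all(f1$archive$gamma >= -1 & f1$archive$gamma <= 1))
  expect_true(all(f1$archive$energy ==
                    pmax(f1$archive$KS_k, f1$archive$KS_c,
                         f1$archive$KS_b, f1$archive$KS_e)))
  f2 <- fit_generative_model(obs, "matching", box = box, schedule = c(0, 1),
                             n_samp = 15, seed_graph = seed, rng_seed = 9)
  expect_identical(f1$archive, f2$archive)

  # the geometric rule searches a 1-D interval
  fg <- fit_generative_model(obs, "geometric", schedule = c(0),
                             n_samp = 10, seed_graph = seed, rng_seed = 9)
  expect_true(all(is.na(fg$archive$gamma)))
})

test_that("a uniform-only schedule samples the box uniformly", {
  cfg <- fixture_config(n = 30, rng_seed = 6)
  obs <- make_observed(cfg)
  seed <- make_seed_graph(make_coords(cfg), cfg$seed_edges)
  box <- parameter_box(eta = c(-4, 1), gamma = c(-1, 1))
  f <- fit_generative_model(obs, "matching", box = box, schedule = 0,
                            n_samp = 60, seed_graph = seed, rng_seed = 10)
  expect_gt(stats::ks.test(f$archive$eta, "punif", -4, 1)$p.value, 0.01)
  expect_gt(stats::ks.test(f$archive$gamma, "punif", -1, 1)$p.value, 0.01)
})

test_that("archive records regrow into the networks that were scored", {
  cfg <- fixture_config(n = 30, rng_seed = 6)
  obs <- make_observed(cfg)
  seed <- make_seed_graph(make_coords(cfg), cfg$seed_edges)
  f <- fit_generative_model(obs, "matching",
                            box = parameter_box(c(-4, 1), c(-1, 1)),
                            schedule = 0, n_samp = 5, seed_graph = seed,
                            rng_seed = 11)
  top <- select_best(f, 0.2)
  nets <- regrow_networks(f, top)
  rec <- network_energy(obs, nets[[1]])
  expect_equal(rec$energy, top$energy[1], tolerance = 1e-12)
})
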