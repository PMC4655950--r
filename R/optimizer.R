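#' Parameter-space box for the Monte Carlo search
#'
#' Rectangular search region for the wiring-rule exponents. The defaults,
#' eta in `[-12, 3]` and gamma in `[-10, 10]`, comfortably contain the
#' fitted means reported for every wiring rule in this model family (eta
#' down to about -4.6, gamma between about -5.9 and 2.5). Pass
#' `gamma = NULL` for the pure geometric rule, which searches a 1-D
#' interval in eta only.
#'
#' @param eta numeric `c(lower, upper)` bounds for eta.
#' @param gamma numeric `c(lower, upper)` bounds for gamma, or `NULL` for a
#'   1-D search.
#' @return An object of class `parameter_box`.
#' @export
parameter_box <- function(eta = c(-12, 3), gamma = c(-10, 10)) {
  check_bounds <- function(b, name) {
    if (!is.numeric(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop(name, " bounds must be c(lower, upper) with lower < upper")
  }
  check_bounds(eta, "eta")
  if (!is.null(gamma)) check_bounds(gamma, "gamma")
  structure(list(eta = eta, gamma = gamma), class = "parameter_box")
}

default_box <- function(rule) {
  if (rule == "geometric") parameter_box(gamma = NULL) else parameter_box()
}

box_dim <- function(box) if (is.null(box$gamma)) 1L else 2L
box_lower <- function(box) c(box$eta[1], box$gamma[1])[seq_len(box_dim(box))]
box_upper <- function(box) c(box$eta[2], box$gamma[2])[seq_len(box_dim(box))]

uniform_in_box <- function(n, box) {
  lo <- box_lower(box)
  hi <- box_upper(box)
  d <- length(lo)
  m <- vapply(seq_len(d), function(j) stats::runif(n, lo[j], hi[j]), numeric(n))
  matrix(m, nrow = n, ncol = d)
}

# index of the nearest generator for each row of `points`
# (Euclidean metric; ties broken by the lowest generator index)
nearest_cell <- function(generators, points) {
  g <- as.matrix(generators)
  p <- matrix(as.matrix(points), ncol = ncol(g))
  d2 <- outer(rowSums(p^2), rowSums(g^2), `+`) - 2 * p %*% t(g)
  max.col(-d2, ties.method = "first")
}

#' Sample Voronoi cells by inverse-energy weighting
#'
#' Draws cell indices i.i.d. with probability proportional to
#' `E_C^(-alpha)`, where `E_C` is the cell's energy. `alpha = 0` searches
#' uniformly across cells; larger `alpha` concentrates sampling in
#' low-energy regions. Energies are floored at `1e-12` so a zero-energy
#' cell cannot produce an infinite weight.
#'
#' @param cell_energies positive numeric vector, one energy per cell
#'   (= per generator point).
#' @param alpha non-negative sampling exponent.
#' @param n_draws number of cells to draw (> 0).
#' @return Integer vector of cell indices of length `n_draws`.
#' @export
sample_cells <- function(cell_energies, alpha, n_draws) {
  if (!is.numeric(n_draws) || length(n_draws) != 1 || n_draws <= 0)
    stop("n_draws must be a positive integer")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0)
    stop("alpha must be non-negative")
  e <- pmax(cell_energies, 1e-12)
  w <- e^(-alpha)
  sample.int(length(e), size = n_draws, replace = TRUE, prob = w / sum(w))
}

#' Sample a point uniformly within one Voronoi cell
#'
#' Rejection sampling: draw uniformly in the box and accept when the
#' nearest generator is the target cell. The cell of a lone generator is
#' the whole box, so a single-generator partition degenerates to uniform
#' box sampling.
#'
#' @param generators matrix of generator points (rows), one per cell.
#' @param cell index of the target cell.
#' @param box a [parameter_box()].
#' @param max_reject cap on rejected draws (default `1e5`); exceeding it
#'   raises an error suggesting the cell has negligible volume.
#' @return Numeric vector: one point inside the cell (length 1 or 2).
#' @export
sample_point_in_cell <- function(generators, cell, box, max_reject = 1e5) {
  generators <- as.matrix(generators)
  if (cell < 1 || cell > nrow(generators)) stop("cell index out of range")
  tried <- 0
  chunk <- 256L
  while (tried < max_reject) {
    m <- min(chunk, max_reject - tried)
    cand <- uniform_in_box(m, box)
    hit <- which(nearest_cell(generators, cand) == cell)
    if (length(hit) > 0) return(cand[hit[1], ])
    tried <- tried + m
  }
  stop("rejection cap (", max_reject, ") exceeded sampling cell ", cell,
       "; the cell may have negligible volume")
}

# Batched equivalent of calling sample_point_in_cell() once per requested
# cell: propose candidate points uniformly in the box, assign each candidate
# to its nearest generator in one vectorized pass, and let every pending
# request consume a matching candidate. A request whose cell attracts no
# candidate within the rejection budget has negligible volume; it is
# redrawn from the cell weights rather than aborting the whole fit.
sample_points_in_cells <- function(generators, cells, box, cell_energies,
                                   alpha, max_reject = 1e5) {
  d <- box_dim(box)
  n_req <- length(cells)
  out <- matrix(NA_real_, n_req, d)
  pending <- seq_len(n_req)
  batch <- max(512L, n_req)
  tried <- 0
  while (length(pending) > 0) {
    if (tried >= max_reject) { # negligible-volume cells: redraw
      cells[pending] <- sample_cells(cell_energies, alpha, length(pending))
      tried <- 0
    }
    cand <- uniform_in_box(batch, box)
    hit <- nearest_cell(generators, cand)
    used <- logical(batch)
    for (i in pending) {
      j <- which(hit == cells[i] & !used)
      if (length(j) > 0) {
        out[i, ] <- cand[j[1], ]
        used[j[1]] <- TRUE
      }
    }
    pending <- pending[is.na(out[pending, 1])]
    tried <- tried + batch
  }
  out
}

#' Fit wiring-rule parameters by Voronoi Monte Carlo search
#'
#' Three-stage procedure, repeated once per entry of `schedule`:
#' (1) sample `n_samp` points in parameter space — uniformly in the box on
#' the first repetition, afterwards from within Voronoi cells of the
#' accumulated archive with cell probability proportional to
#' `E_C^(-alpha)`; (2) evaluate each point by growing
#' `networks_per_point` synthetic networks and scoring them with
#' [network_energy()] against the observed network; (3) re-partition the
#' space by a Voronoi tessellation over all archived points. The default
#' schedule anneals `alpha` through 0, 0.5, 1, 1.5, 2: early repetitions
#' explore, later ones concentrate on low-energy regions. The full fit is
#' reproducible bit-for-bit given `rng_seed`.
#'
#' @param observed the target `spatial_graph`.
#' @param rule one of [wiring_rule_names()].
#' @param box a [parameter_box()]; defaults to [default_box()] for the
#'   rule (1-D in eta for the geometric rule).
#' @param schedule numeric vector of alpha values, one per repetition.
#' @param n_samp points sampled per repetition (default 2000, giving a
#'   10,000-point archive under the default five-repetition schedule).
#' @param networks_per_point synthetic networks grown per parameter point;
#'   the recorded energy is the mean over them (default 1).
#' @param seed_graph seed network for every growth; defaults to an
#'   edgeless graph on the observed coordinates.
#' @param M target edge count; defaults to the observed edge count.
#' @param epsilon kernel regularizer (default `1e-6`).
#' @param geometric_kernel `"powerlaw"` or `"exponential"`.
#' @param rng_seed integer seed for the whole fit.
#' @param verbose print one line per repetition.
#' @return An object of class `gnm_fit` whose `archive` is a data frame
#'   with one row per evaluated point: `rep`, `alpha`, `eta`, `gamma`
#'   (`NA` for the geometric rule), the four KS components, `energy` and
#'   `growth_seed` (the RNG seed that regenerates the point's first
#'   network).
#' @export
fit_generative_model <- function(observed, rule, box = NULL,
                                 schedule = c(0, 0.5, 1, 1.5, 2),
                                 n_samp = 2000, networks_per_point = 1,
                                 seed_graph = NULL, M = NULL, epsilon = 1e-6,
                                 geometric_kernel = c("powerlaw", "exponential"),
                                 rng_seed = NULL, verbose = FALSE) {
  geometric_kernel <- match.arg(geometric_kernel)
  rule <- match_rule(rule)
  if (!is_spatial_graph(observed)) stop("observed must be a spatial_graph")
  if (is.null(box)) box <- default_box(rule)
  if (rule == "geometric" && box_dim(box) != 1)
    stop("the geometric rule searches a 1-D box; use parameter_box(gamma = NULL)")
  if (n_samp < 1) stop("n_samp must be at least 1")
  if (is.null(seed_graph))
    seed_graph <- spatial_graph(matrix(0, observed$n, observed$n),
                                observed$coords, observed$labels)
  if (is.null(M)) M <- edge_count(observed)
  d <- box_dim(box)

  D <- euclidean_distances(observed$coords)
  obs_stats <- node_statistics(observed)
  obs_lengths <- edge_lengths(observed, D)
  seedA <- seed_graph$adjacency
  storage.mode(seedA) <- "integer"
  if (!is.null(rng_seed)) set.seed(rng_seed)

  eval_point <- function(eta, gamma) {
    gseeds <- sample.int(.Machine$integer.max, networks_per_point)
    comps <- matrix(0, networks_per_point, 4)
    energies <- numeric(networks_per_point)
    for (j in seq_len(networks_per_point)) {
      set.seed(gseeds[j])
      res <- .grow_cpp(seedA, distance_term(D, eta, geometric_kernel),
                       if (rule == "geometric") 0 else gamma,
                       epsilon, as.integer(M), rule)
      comps[j, ] <- energy_components(obs_stats, obs_lengths,
                                      res$adjacency, D)
      energies[j] <- max(comps[j, ])
    }
    c(colMeans(comps), mean(energies), gseeds[1])
  }

  pts_all <- matrix(numeric(0), ncol = d)
  energies_all <- numeric(0)
  rows <- vector("list", length(schedule))

  for (r in seq_along(schedule)) {
    alpha <- schedule[r]
    pts <- if (r == 1) {
      uniform_in_box(n_samp, box)
    } else {
      cells <- sample_cells(energies_all, alpha, n_samp)
      sample_points_in_cells(pts_all, cells, box, energies_all, alpha)
    }
    ev <- matrix(0, n_samp, 6)
    for (i in seq_len(n_samp))
      ev[i, ] <- eval_point(pts[i, 1], if (d == 2) pts[i, 2] else 0)
    rows[[r]] <- data.frame(
      rep = r, alpha = alpha,
      eta = pts[, 1],
      gamma = if (d == 2) pts[, 2] else NA_real_,
      KS_k = ev[, 1], KS_c = ev[, 2], KS_b = ev[, 3], KS_e = ev[, 4],
      energy = ev[, 5], growth_seed = as.integer(ev[, 6]))
    pts_all <- rbind(pts_all, pts)
    energies_all <- c(energies_all, ev[, 5])
    if (verbose)
      message(sprintf("repetition %d (alpha = %.1f): min energy %.4f",
                      r, alpha, min(energies_all)))
  }

  structure(list(archive = do.call(rbind, rows), rule = rule, box = box,
                 schedule = schedule, n_samp = n_samp,
                 networks_per_point = networks_per_point, M = M,
                 epsilon = epsilon, geometric_kernel = geometric_kernel,
                 rng_seed = rng_seed, seed_graph = seed_graph,
                 coords = observed$coords),
            class = "gnm_fit")
}

#' @export
print.gnm_fit <- function(x, ...) {
  best <- x$archive[which.min(x$archive$energy), ]
  cat(sprintf("<gnm_fit> rule %s, %d evaluated points, min energy %.4f at eta = %.3f%s\n",
              x$rule, nrow(x$archive), best$energy, best$eta,
              if (is.na(best$gamma)) "" else sprintf(", gamma = %.3f", best$gamma)))
  invisible(x)
}

#' Lowest-energy subset of an archive
#'
#' Returns the `ceiling(fraction * nrow)` lowest-energy records,
#' stable-sorted so ties keep their insertion order. With the default
#' 10,000-point archive and `fraction = 0.01` this is the top-1% ensemble
#' of 100 networks used for parameter estimates and cross-validation.
#'
#' @param archive a `gnm_fit` object or its archive data frame.
#' @param fraction fraction of records to keep, in `(0, 1]`.
#' @return Data frame of the selected records.
#' @export
select_best <- function(archive, fraction = 0.01) {
  if (inherits(archive, "gnm_fit")) archive <- archive$archive
  if (nrow(archive) == 0) stop("archive is empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  keep <- ceiling(fraction * nrow(archive))
  archive[order(archive$energy)[seq_len(keep)], , drop = FALSE]
}

#' Regenerate the synthetic networks behind archive records
#'
#' Replays the recorded growth seed of each archive row, producing the
#' synthetic network that was scored there (the first network of the
#' point, when several were grown per point).
#'
#' @param fit a `gnm_fit` object.
#' @param records archive rows (e.g. from [select_best()]).
#' @return List of `spatial_graph`s.
#' @export
regrow_networks <- function(fit, records) {
  D <- euclidean_distances(fit$coords)
  lapply(seq_len(nrow(records)), function(i) {
    p <- generative_params(eta = records$eta[i],
                           gamma = if (is.na(records$gamma[i])) 0 else records$gamma[i],
                           epsilon = fit$epsilon, M = fit$M)
    grow_network(fit$seed_graph, fit$rule, p,
                 rng_seed = records$growth_seed[i],
                 geometric_kernel = fit$geometric_kernel,
                 distances = D)$graph
  })
}
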