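# Shared fixtures, built in code.

# Two-activity toy panel, one activity per sodium class.
toy_panel <- function(km_indep = 0.05, km_dep = 2.0) {
  candidate_panel(list(
    kinetic_activity("fast", "GENE_A", km = km_indep, sodium_dependent = FALSE,
                     mechanism = "uniporter"),
    kinetic_activity("slow", "GENE_B", km = km_dep, sodium_dependent = TRUE,
                     mechanism = "symporter")
  ))
}

# A normalized dataset simulated from a given truth on a given panel.
simulated_normalized <- function(panel = default_panel(),
                                 true_vmax = default_truth(),
                                 noise_scale = 0, seed = 1, ...) {
  sim <- simulate_uptake(panel = panel, true_vmax = true_vmax,
                         noise_scale = noise_scale, seed = seed, ...)
  list(dataset = normalize_dataset(sim$dataset), truth = sim$truth)
}

# Exhaustive grid search of the weighted RSS over a 2-parameter Vmax
# grid; the brute-force oracle for the optimizer.
grid_search_2d <- function(dataset, panel, vmax_max = 3, step = 0.01) {
  y <- dataset$rate_mean
  w <- if (all(dataset$rate_sd > 0)) 1 / dataset$rate_sd^2 else rep(1, length(y))
  X <- sapply(1:2, function(i) {
    gate <- dataset$buffer == "sodium" | !panel$sodium_dependent[i]
    as.numeric(gate) * dataset$concentration_mM /
      (panel$km_mM[i] + dataset$concentration_mM)
  })
  g <- seq(0, vmax_max, by = step)
  V <- as.matrix(expand.grid(v1 = g, v2 = g))
  resid <- matrix(y, nrow = length(y), ncol = nrow(V)) - X %*% t(V)
  rss <- colSums(w * resid^2)
  best <- which.min(rss)
  list(vmax = V[best, ], rss = rss[best], step = step)
}

# Distance between the optimizer's and the grid's minimizers in units
# of one grid cell, measured in the least-squares objective's metric
# (q(d) = sum w * (X d)^2). This accounts for parameter correlation:
# along a flat valley the lattice argmin can sit several cells from the
# continuous optimum while being indistinguishable at the grid's
# resolution; a stalled optimizer still shows up as a distance >> 1.
grid_cell_distance <- function(fit, grid, dataset, panel) {
  y <- dataset$rate_mean
  w <- if (all(dataset$rate_sd > 0)) 1 / dataset$rate_sd^2 else rep(1, length(y))
  X <- sapply(seq_len(nrow(panel)), function(i) {
    gate <- dataset$buffer == "sodium" | !panel$sodium_dependent[i]
    as.numeric(gate) * dataset$concentration_mM /
      (panel$km_mM[i] + dataset$concentration_mM)
  })
  q <- function(d) sum(w * as.numeric(X %*% d)^2)
  delta <- unname(grid$vmax) - unname(fit$vmax)
  cell <- max(q(grid$step * c(1, 0)), q(grid$step * c(0, 1)),
              q(grid$step * c(1, 1)), q(grid$step * c(1, -1)))
  sqrt(q(delta) / cell)
}
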