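test_that("noiseless four-activity truth is recovered with the correct zero set", {
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0)
  fit <- fit_species_global(sim$dataset, p, seed = 11)
  truth <- sim$truth$true_vmax_normalized
  nonzero <- truth > 0
  expect_true(fit$converged)
  expect_lt(max(abs(fit$vmax[nonzero] - truth[nonzero]) / truth[nonzero]), 1e-3)
  expect_true(all(c("ASCT2", "y+LAT2", "b0+AT", "LAT4_high") %in%
                    fit$zero_activity_set))
  expect_false(any(c("B0AT2", "y+LAT1", "LAT1", "LAT4_low") %in%
                     fit$zero_activity_set))
  expect_gte(fit$n_starts_converged, 1L)
})

test_that("a sodium-independent-only truth zeroes every sodium-dependent activity", {
  p <- default_panel()
  tv <- setNames(rep(0, 8), p$activity_id)
  tv["LAT4_low"] <- 5
  sim <- simulated_normalized(true_vmax = tv, noise_scale = 0)
  fit <- fit_species_global(sim$dataset, p, seed = 3)
  expect_true(all(p$activity_id[p$sodium_dependent] %in% fit$zero_activity_set))
  # with no sodium-dependent flux the two buffer curves coincide
  d <- na_dependent_difference(sim$dataset)
  expect_equal(d$difference, rep(0, nrow(d)), tolerance = 1e-12)
})

test_that("optimizer minimum matches the exhaustive grid search on a 2-activity toy", {
  toy <- toy_panel()
  tv <- c(fast = 0.4, slow = 0.8)
  sim <- simulated_normalized(panel = toy, true_vmax = tv,
                              noise_scale = 0.05, seed = 17)
  fit <- fit_species_global(sim$dataset, toy, seed = 17)
  grid <- grid_search_2d(sim$dataset, toy, vmax_max = 3, step = 0.01)
  # exhaustive enumeration never beats the optimizer, and the two
  # minimizers are one grid cell apart at the objective's resolution
  expect_lte(fit$rss, grid$rss + 1e-9)
  expect_lte(grid_cell_distance(fit, grid, sim$dataset, toy), 1)
})

test_that("optimizer agrees with the non-negative least-squares closed solution", {
  # with fixed Km the mixture is linear in Vmax, so NNLS is an
  # independent oracle for the bounded iterative fit
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0.05, seed = 23)
  fit <- fit_species_global(sim$dataset, p, seed = 23)
  ds <- sim$dataset
  w <- 1 / ds$rate_sd^2
  X <- sapply(seq_len(nrow(p)), function(i) {
    gate <- ds$buffer == "sodium" | !p$sodium_dependent[i]
    as.numeric(gate) * ds$concentration_mM / (p$km_mM[i] + ds$concentration_mM)
  })
  nnls <- pracma::lsqnonneg(sqrt(w) * X, sqrt(w) * ds$rate_mean)
  expect_equal(unname(fit$vmax), nnls$x, tolerance = 1e-4)
  expect_equal(fit$rss, nnls$resid.norm, tolerance = 1e-6)
})

test_that("restricted fit freezes excluded activities and adjusts DOF", {
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0)
  full <- fit_species_global(sim$dataset, p, seed = 5)
  all_kept <- fit_species_restricted(sim$dataset, p, keep = p$activity_id,
                                     seed = 5)
  expect_equal(all_kept$vmax, full$vmax, tolerance = 1e-10)
  expect_identical(all_kept$dof, full$dof)

  keep3 <- c("B0AT2", "LAT1", "LAT4_low")
  restricted <- fit_species_restricted(sim$dataset, p, keep = keep3, seed = 5)
  expect_identical(restricted$dof, full$dof + 5L)
  expect_true(all(restricted$vmax[setdiff(p$activity_id, keep3)] == 0))
  expect_identical(sort(restricted$frozen), sort(setdiff(p$activity_id, keep3)))

  expect_error(fit_species_restricted(sim$dataset, p, keep = character(0)),
               "at least one")
  expect_error(fit_species_restricted(sim$dataset, p, keep = "SNAT1"), "unknown")
})

test_that("three-activity truth: restricted recovery and no full-model advantage", {
  p <- default_panel()
  tv <- setNames(rep(0, 8), p$activity_id)
  tv[c("B0AT2", "LAT1", "LAT4_low")] <- c(0.530, 0.127, 6.97)
  sim <- simulated_normalized(true_vmax = tv, noise_scale = 0)
  truth <- sim$truth$true_vmax_normalized
  keep3 <- c("B0AT2", "LAT1", "LAT4_low")
  restricted <- fit_species_restricted(sim$dataset, p, keep = keep3, seed = 7)
  expect_lt(max(abs(restricted$vmax[keep3] - truth[keep3]) / truth[keep3]), 0.01)
  full <- fit_species_global(sim$dataset, p, seed = 7)
  expect_gte(restricted$adjusted_r2, full$adjusted_r2 - 1e-9)
})

test_that("model comparison reports deltas and guards its preconditions", {
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0)
  full <- fit_species_global(sim$dataset, p, seed = 2)
  cmp_self <- compare_models(full, full)
  expect_equal(cmp_self$delta_adjusted_r2, 0)
  expect_equal(cmp_self$delta_reduced_chi2, 0)

  restricted <- fit_species_restricted(sim$dataset, p,
                                       keep = c("B0AT2", "y+LAT1", "LAT1",
                                                "LAT4_low"), seed = 2)
  cmp <- compare_models(full, restricted)
  # nested truth, noiseless: same (near-zero) RSS over more DOF
  expect_lte(cmp$delta_reduced_chi2, 1e-10)
  expect_match(cmp$verdict, "free parameters")

  other <- simulated_normalized(noise_scale = 0.05, seed = 99)
  fit_other <- fit_species_global(other$dataset, p, seed = 2)
  expect_error(compare_models(fit_other, restricted), "identical data")

  not_nested <- fit_species_restricted(sim$dataset, p, keep = "ASCT2", seed = 2)
  expect_error(compare_models(restricted, not_nested), "subset")
})

test_that("a useless extra parameter does not usually raise adjusted R2", {
  toy <- candidate_panel(list(
    kinetic_activity("real", "G1", 0.05, FALSE, "uniporter"),
    kinetic_activity("idle", "G2", 0.8, TRUE, "symporter")))
  tv <- c(real = 1.0, idle = 0)
  wins <- 0L
  for (s in 1:100) {
    sim <- simulated_normalized(panel = toy, true_vmax = tv,
                                noise_scale = 0.05, seed = s)
    full <- fit_species_global(sim$dataset, toy, n_starts = 4, seed = s)
    restr <- fit_species_restricted(sim$dataset, toy, keep = "real",
                                    n_starts = 4, seed = s)
    if (full$adjusted_r2 <= restr$adjusted_r2 + 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 80L)
})

test_that("near-collinear sodium-dependent trio triggers the degeneracy flag", {
  p <- default_panel()
  tv <- setNames(rep(0, 8), p$activity_id)
  tv["B0AT2"] <- 0.5
  sim <- simulated_normalized(true_vmax = tv, noise_scale = 0.05, seed = 41)
  trio <- c("B0AT2", "y+LAT2", "ASCT2")  # Km 0.160 / 0.236 / 0.367 mM
  fit <- fit_species_restricted(sim$dataset, p, keep = trio, seed = 41)
  expect_true(fit$ill_conditioned)
  expect_false(fit$se_reliable)
  expect_gt(fit$jacobian_condition, 30)
  # the collinearity inflates at least one SE past its estimate
  rel_se <- fit$se[trio] / pmax(fit$vmax[trio], .Machine$double.eps)
  expect_gt(max(rel_se), 1)

  # a well-separated design is not flagged
  apart <- fit_species_restricted(sim$dataset, p,
                                  keep = c("B0AT2", "LAT1", "LAT4_low"),
                                  seed = 41)
  expect_false(apart$ill_conditioned)
})

test_that("fitted Vmax are never negative and bound-huggers join the zero set", {
  p <- default_panel()
  for (s in 1:20) {
    sim <- simulated_normalized(noise_scale = 0.1, seed = 100 + s)
    fit <- fit_species_global(sim$dataset, p, n_starts = 6, seed = s)
    expect_true(all(fit$vmax >= 0))
    tiny <- fit$vmax > 0 & fit$vmax < fit$zero_tol * max(fit$vmax)
    expect_true(all(names(fit$vmax)[tiny] %in% fit$zero_activity_set))
  }
})

test_that("contribution curves are additive and respect the zero set", {
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0)
  fit <- fit_species_global(sim$dataset, p, seed = 9)
  curves <- species_contribution_curves(fit)
  expect_equal(curves$total, rowSums(curves[, p$activity_id]), tolerance = 1e-12)
  expect_equal(curves$total,
               panel_rate(p, unname(fit$vmax), curves$s_mM, "sodium"),
               tolerance = 1e-12)
  # frozen/zeroed species contribute identically-zero curves
  for (id in fit$zero_activity_set) {
    expect_lt(max(curves[[id]]), 1e-4 * max(curves$total))
  }
  # with the four-activity values, the low-affinity LAT4 component
  # outstrips each of the other three at 1 mM
  at1 <- curves[curves$s_mM == 1, ]
  for (id in c("B0AT2", "y+LAT1", "LAT1")) {
    expect_gt(at1$LAT4_low, at1[[id]])
  }
})

test_that("single-buffer data warns that sodium-dependent species are unidentifiable", {
  p <- default_panel()
  sim <- simulated_normalized(noise_scale = 0)
  only_free <- uptake_dataset(
    as.data.frame(sim$dataset)[sim$dataset$buffer == "sodium_free", ],
    normalized = TRUE)
  expect_warning(fit <- fit_species_global(only_free, p, seed = 1),
                 "single buffer")
  expect_true(fit$single_buffer)
  # sodium-dependent columns are all-zero: conditioning must be degenerate
  expect_true(is.infinite(fit$jacobian_condition))
})

test_that("unnormalized input is rejected with guidance", {
  p <- default_panel()
  sim <- simulate_uptake(noise_scale = 0, seed = 1)
  expect_error(fit_species_global(sim$dataset, p), "normalize")
})
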