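# Study-shaped synthetic data: uptake experiments on the assayed
# 13-concentration grid in both buffers with replicate noise, qPCR CT
# tables, and primer dilution series — each with a known ground truth
# so every pipeline stage is testable end to end.

#' The assayed leucine concentration grid
#'
#' The 13 concentrations (0.01, 4, 10, 12, 20, 30, 50, 40, 100, 120,
#' 300, 400, 1000 uM) converted to mM, in assay order. The 0.01 uM
#' point is the tracer-only condition.
#'
#' @return Numeric vector, mM.
#' @export
default_concentrations <- function() {
  c(0.01, 4, 10, 12, 20, 30, 50, 40, 100, 120, 300, 400, 1000) / 1000
}

#' The four-activity ground truth used as simulation default
#'
#' Per-activity maximal rates (normalized rate units) with nonzero
#' values for B0AT2, y+LAT1, LAT1 and LAT4_low and zero for the other
#' four activities of [default_panel()].
#'
#' @return Named numeric vector in default-panel order.
#' @export
default_truth <- function() {
  v <- stats::setNames(rep(0, 8), default_panel()$activity_id)
  v["B0AT2"] <- 0.2492
  v["y+LAT1"] <- 0.2161
  v["LAT1"] <- 0.0927
  v["LAT4_low"] <- 7.448
  v
}

#' Simulate a replicate uptake experiment
#'
#' Draws per-replicate rates around the panel forward model at each
#' (concentration, buffer) pair, then aggregates to the mean/SD/n form
#' of a real uptake table. Noise is proportional (a coefficient of
#' variation, the default, matching error bars that grow with the
#' mean) or additive; negative replicate draws are truncated at zero
#' and counted. Output is raw-scale (`normalized = FALSE`); the ground
#' truth sidecar carries both the generating Vmax vector and its
#' equivalent on the normalized scale (`true_vmax /` forward rate at
#' the reference concentration in sodium buffer), which is what a fit
#' of the normalized data recovers.
#'
#' @param panel An `aat_panel` (default [default_panel()]).
#' @param true_vmax Per-activity ground-truth Vmax vector (default
#'   [default_truth()]).
#' @param concentrations_mM Assay grid, mM (default
#'   [default_concentrations()]).
#' @param n_replicates Replicates ("filters") per point, default 8.
#' @param noise_model `"cv"` (proportional, default) or `"additive"`.
#' @param noise_scale CV (default 0.05) or additive SD.
#' @param reference_mM Normalization reference recorded on the dataset.
#' @param seed RNG seed; required for nonzero noise.
#' @return List: `dataset` (raw `uptake_dataset`), `truth` (list with
#'   `true_vmax`, `true_vmax_normalized`, `reference_rate`, `config`,
#'   `n_truncated`).
#' @export
simulate_uptake <- function(panel = default_panel(), true_vmax = default_truth(),
                            concentrations_mM = default_concentrations(),
                            n_replicates = 8L,
                            noise_model = c("cv", "additive"),
                            noise_scale = 0.05, reference_mM = 0.3, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(panel, "aat_panel"))
  if (length(true_vmax) != nrow(panel)) {
    stop("`true_vmax` must have one entry per panel activity", call. = FALSE)
  }
  if (!is.numeric(noise_scale) || noise_scale < 0) {
    stop("`noise_scale` must be >= 0", call. = FALSE)
  }
  if (noise_scale > 0 && is.null(seed)) {
    stop("`seed` is required for stochastic output", call. = FALSE)
  }
  if (any(concentrations_mM < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  grid <- expand.grid(concentration_mM = concentrations_mM,
                      buffer = BUFFER_LEVELS, stringsAsFactors = FALSE)
  n_trunc <- 0L
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mu <- panel_rate(panel, unname(true_vmax), grid$concentration_mM[i],
                     grid$buffer[i])
    reps <- if (noise_scale == 0) rep(mu, n_replicates) else {
      eps <- stats::rnorm(n_replicates)
      if (noise_model == "cv") mu * (1 + noise_scale * eps)
      else mu + noise_scale * eps
    }
    n_trunc <<- n_trunc + sum(reps < 0)
    reps <- pmax(reps, 0)
    data.frame(concentration_mM = grid$concentration_mM[i],
               buffer = grid$buffer[i],
               rate_mean = mean(reps),
               rate_sd = if (n_replicates > 1L) stats::sd(reps) else 0,
               n = n_replicates, stringsAsFactors = FALSE)
  })
  dataset <- uptake_dataset(do.call(rbind, rows), normalized = FALSE,
                            reference_mM = reference_mM)
  ref_rate <- panel_rate(panel, unname(true_vmax), reference_mM, "sodium")
  truth <- list(
    true_vmax = stats::setNames(as.numeric(true_vmax), panel$activity_id),
    true_vmax_normalized =
      stats::setNames(as.numeric(true_vmax) / ref_rate, panel$activity_id),
    reference_rate = ref_rate,
    n_truncated = n_trunc,
    config = list(concentrations_mM = concentrations_mM,
                  n_replicates = n_replicates, noise_model = noise_model,
                  noise_scale = noise_scale, reference_mM = reference_mM,
                  seed = seed)
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a primer dilution series
#'
#' Generates CT values along `CT = intercept - log10(ng) /
#' log10(amplification)` with optional Gaussian scatter, so that with
#' zero noise [primer_efficiency()] recovers `amplification - 1`
#' exactly.
#'
#' @param amplification Per-cycle amplification factor (> 1); 2 is
#'   perfect doubling.
#' @param intercept_ct CT at 1 ng input, default 30.
#' @param ng_per_reaction Template inputs, ng (default a 4-point
#'   ten-fold series 0.1-100 ng).
#' @param noise_sd CT scatter SD, default 0.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return data.frame `ng_per_reaction`, `ct` suitable for
#'   [primer_efficiency()].
#' @export
simulate_dilution_series <- function(amplification = 2, intercept_ct = 30,
                                     ng_per_reaction = c(0.1, 1, 10, 100),
                                     noise_sd = 0, seed = 1L) {
  if (!is.numeric(amplification) || amplification <= 1) {
    stop("`amplification` must be > 1", call. = FALSE)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required for stochastic output", call. = FALSE)
    set.seed(seed)
  }
  ct <- intercept_ct - log10(ng_per_reaction) / log10(amplification)
  if (noise_sd > 0) ct <- ct + stats::rnorm(length(ct), sd = noise_sd)
  data.frame(ng_per_reaction = ng_per_reaction, ct = ct)
}

#' Simulate a qPCR CT table with known relative expression
#'
#' Reference-gene CTs are drawn around `reference_ct_mean`; each target
#' gene's CT mean sits `log2(true_rel_expr)` cycles below it (more
#' expression, earlier threshold), so with zero noise the comparative
#' CT pipeline recovers `true_rel_expr` exactly. `true_rel_expr` may be
#' a named vector (one condition) or a genes x conditions matrix.
#'
#' @param true_rel_expr Named vector, or matrix with rownames = genes
#'   and colnames = conditions, of expression relative to the
#'   reference gene. All values > 0.
#' @param reference_ct_mean Reference-gene CT level, default 18.85.
#' @param ct_noise_sd Technical CT scatter, default 0.
#' @param n_technical Technical replicates per reaction, default 3.
#' @param condition Condition label when `true_rel_expr` is a vector.
#' @param reference_gene Reference gene symbol, default `"HPRT"`.
#' @param seed RNG seed (required when `ct_noise_sd > 0`).
#' @return List: `ct_table` (long data.frame `gene`, `condition`,
#'   `replicate`, `ct`, `is_reference`, `is_control`), `truth`.
#' @export
simulate_ct_table <- function(true_rel_expr, reference_ct_mean = 18.85,
                              ct_noise_sd = 0, n_technical = 3L,
                              condition = "RM", reference_gene = "HPRT",
                              seed = 1L) {
  if (is.matrix(true_rel_expr)) {
    expr <- true_rel_expr
  } else {
    if (is.null(names(true_rel_expr))) {
      stop("`true_rel_expr` must be named by gene", call. = FALSE)
    }
    expr <- matrix(true_rel_expr, ncol = 1,
                   dimnames = list(names(true_rel_expr), condition))
  }
  if (any(!is.finite(expr)) || any(expr <= 0)) {
    stop("all true relative expressions must be finite and > 0", call. = FALSE)
  }
  if (n_technical < 1L) stop("`n_technical` must be >= 1", call. = FALSE)
  if (ct_noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is required for stochastic output", call. = FALSE)
    set.seed(seed)
  }
  draw <- function(mu) {
    if (ct_noise_sd == 0) rep(mu, n_technical)
    else mu + stats::rnorm(n_technical, sd = ct_noise_sd)
  }
  rows <- list()
  for (cond in colnames(expr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = reference_gene, condition = cond,
      replicate = seq_len(n_technical), ct = draw(reference_ct_mean),
      is_reference = TRUE, is_control = FALSE, stringsAsFactors = FALSE)
    for (g in rownames(expr)) {
      mu <- reference_ct_mean - log2(expr[g, cond])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = seq_len(n_technical),
        ct = draw(mu), is_reference = FALSE, is_control = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  ct_table <- do.call(rbind, rows)
  rownames(ct_table) <- NULL
  list(ct_table = ct_table,
       truth = list(true_rel_expr = expr, reference_ct_mean = reference_ct_mean,
                    ct_noise_sd = ct_noise_sd, n_technical = n_technical,
                    reference_gene = reference_gene, seed = seed))
}
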