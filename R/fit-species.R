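# Global constrained deconvolution: one shared per-activity Vmax vector
# fitted to sodium and sodium-free uptake curves simultaneously, with
# sodium gating supplying the buffer contrast. Km values are fixed
# literature affinities and are never refit, so the free parameters are
# the non-negative Vmax,i.

# Active-set refinement of a non-negative linear least-squares
# solution. With Km fixed the mixture model is linear in Vmax, so the
# weighted problem min ||Xw v - yw||^2, v >= 0 is convex; this polishes
# an iterate (e.g. a Levenberg-Marquardt endpoint, whose projected
# bound handling can stall under widely spread weights) to the exact
# constrained optimum: solve ordinary LS on the positive support,
# drop negative coefficients, and admit zeroed coordinates whose
# gradient shows they would reduce the residual.
refine_active_set <- function(Xw, yw, v0, max_iter = 100L) {
  p <- ncol(Xw)
  P <- v0 > 1e-12 * max(v0, 0)
  v <- rep(0, p)
  solve_on <- function(P) {
    sol <- qr.coef(qr(Xw[, P, drop = FALSE]), yw)
    sol[is.na(sol)] <- 0
    sol
  }
  for (it in seq_len(max_iter)) {
    if (any(P)) {
      sol <- solve_on(P)
      guard <- 0L
      while (any(sol < 0) && (guard <- guard + 1L) <= p) {
        idxP <- which(P)
        P[idxP[which.min(sol)]] <- FALSE
        if (!any(P)) break
        sol <- solve_on(P)
      }
      v <- rep(0, p)
      if (any(P)) v[P] <- pmax(sol, 0)
    } else {
      v <- rep(0, p)
    }
    grad <- as.numeric(crossprod(Xw, yw - Xw %*% v))
    scale <- max(1, max(abs(grad)))
    cand <- which(!P & grad > 1e-10 * scale)
    if (!length(cand)) break
    P[cand[which.max(grad[cand])]] <- TRUE
  }
  v
}

# Design matrix: rows = observations, cols = activities;
# entry = gate(activity, buffer) * s / (Km_i + s).
species_design <- function(panel, concentration_mM, buffer) {
  X <- sapply(seq_len(nrow(panel)), function(i) {
    gate <- ifelse(buffer == "sodium", TRUE, !panel$sodium_dependent[i])
    as.numeric(gate) * concentration_mM / (panel$km_mM[i] + concentration_mM)
  })
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  colnames(X) <- panel$activity_id
  X
}

#' Global fit of per-species maximal transport rates
#'
#' Estimates the per-activity Vmax vector of a sodium-gated
#' Michaelis-Menten mixture by weighted least squares over all
#' observations in both buffers simultaneously, assuming each
#' activity's maximal rate is the same in every buffer. Bound
#' constraints keep every Vmax,i >= 0; optimization is
#' Levenberg-Marquardt from multiple seeded log-uniform random starts,
#' each endpoint polished by an active-set refinement (exact for this
#' linear-in-Vmax problem), the best residual sum of squares winning
#' (ties broken by the smallest parameter norm). Estimates that collapse against the zero
#' bound are reported in the zero-activity set.
#'
#' @param dataset A normalized `uptake_dataset`, ideally with both
#'   buffer conditions. With a single buffer the fit proceeds with a
#'   warning: sodium-dependent activities are then unidentifiable.
#' @param panel An `aat_panel`; Km and sodium flags are taken from it.
#' @param keep Optional character vector of activity_ids to fit; all
#'   others are frozen at 0 and excluded from DOF accounting (used by
#'   [fit_species_restricted()]).
#' @param weights `"auto"` (1/sd^2 when all SDs positive, the default),
#'   `"1/sd2"`, or `"none"`.
#' @param n_starts Number of random multi-starts (default 16).
#' @param zero_tol Relative threshold: estimates below
#'   `zero_tol * max(vmax_i)` join the zero-activity set.
#' @param seed RNG seed for the multi-start initializations.
#' @param cond_threshold Jacobian condition number above which the fit
#'   is flagged ill-conditioned and SEs marked unreliable. The default
#'   30 is the conventional condition-index bound for serious
#'   collinearity.
#' @return A `species_fit` object; see Details.
#' @details The returned list carries the per-activity estimates
#'   (`vmax`, `se`, `zero_activity_set`), fit statistics (`rss`, `dof`,
#'   `reduced_chi2`, `adjusted_r2`), the numerical-conditioning
#'   indicator `jacobian_condition` with flag `ill_conditioned`,
#'   multi-start agreement (`n_starts_converged` of `n_starts`), the
#'   `seed`, the weighting scheme, and the data it was fitted to.
#' @export
fit_species_global <- function(dataset, panel, keep = NULL,
                               weights = c("auto", "1/sd2", "none"),
                               n_starts = 16L, zero_tol = 1e-4, seed = 1L,
                               cond_threshold = 30) {
  weights <- match.arg(weights)
  stopifnot(inherits(dataset, "uptake_dataset"), inherits(panel, "aat_panel"))
  if (!is_normalized(dataset)) {
    stop("`dataset` must be normalized (see normalize_dataset())", call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (is.null(keep)) keep <- panel$activity_id
  unknown <- setdiff(keep, panel$activity_id)
  if (length(unknown)) {
    stop("unknown activity_id in `keep`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) == 0L) stop("`keep` must name at least one activity", call. = FALSE)

  buffers_present <- unique(dataset$buffer)
  single_buffer <- length(buffers_present) < 2L
  if (single_buffer) {
    warning("dataset contains a single buffer condition (", buffers_present,
            "); sodium-dependent and -independent activities are not separable")
  }

  y <- dataset$rate_mean
  wt <- fit_weights(dataset$rate_sd, weights)
  w <- wt$w
  X <- species_design(panel, dataset$concentration_mM, dataset$buffer)
  free <- match(keep, panel$activity_id)
  Xf <- X[, free, drop = FALSE]
  p <- length(free)
  n <- length(y)
  if (n - p < 1L) {
    stop("not enough observations (", n, ") for ", p, " free parameters",
         call. = FALSE)
  }

  sw <- sqrt(w)
  resid_fn <- function(v) sw * (y - as.numeric(Xf %*% v))

  set.seed(seed)
  starts <- matrix(10^stats::runif(n_starts * p, min = -3, max = 1),
                   nrow = n_starts)
  Xw <- sw * Xf
  yw <- sw * y
  sols <- vector("list", n_starts)
  rss_all <- rep(NA_real_, n_starts)
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[k, ], fn = resid_fn,
                         lower = rep(0, p),
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$par))) {
      # polish the LM endpoint to the exact constrained optimum of the
      # (linear-in-Vmax) problem
      sols[[k]] <- refine_active_set(Xw, yw, pmax(fit$par, 0))
      rss_all[k] <- sum(resid_fn(sols[[k]])^2)
    }
  }
  ok <- which(is.finite(rss_all))
  if (length(ok) == 0L) {
    warning("optimizer failed to converge from any start")
    return(structure(list(converged = FALSE, n_starts = n_starts,
                          n_starts_converged = 0L, seed = seed),
                     class = "species_fit"))
  }
  best_rss <- min(rss_all[ok])
  # starts that reached (numerically) the same minimum
  near <- ok[rss_all[ok] <= best_rss + 1e-8 * (1 + best_rss)]
  norms <- vapply(sols[near], function(v) sqrt(sum(v^2)), numeric(1))
  vhat_free <- sols[[near[which.min(norms)]]]
  rss <- sum(resid_fn(vhat_free)^2)

  vmax <- stats::setNames(rep(0, nrow(panel)), panel$activity_id)
  vmax[free] <- pmax(vhat_free, 0)

  dof <- n - p
  chi2 <- reduced_chi2(rss, n, p)
  tss <- weighted_tss(y, w)
  ar2 <- if (n - p - 1 >= 1 && tss > 0) adjusted_r2(rss, tss, n, p) else NA_real_

  # conditioning of the weighted design restricted to free parameters
  Jw <- Xw
  d <- svd(Jw, nu = 0, nv = 0)$d
  jac_cond <- if (min(d) > 0) max(d) / min(d) else Inf
  ill <- jac_cond > cond_threshold

  cov <- chi2 * pseudo_inverse(crossprod(Jw))
  se <- stats::setNames(rep(NA_real_, nrow(panel)), panel$activity_id)
  se[free] <- sqrt(pmax(diag(cov), 0))

  vmax_max <- max(vmax)
  zero_set <- if (vmax_max > 0) {
    names(vmax)[vmax < zero_tol * vmax_max]
  } else {
    names(vmax)
  }

  structure(list(
    vmax = vmax, se = se, zero_activity_set = zero_set,
    keep = keep, frozen = setdiff(panel$activity_id, keep),
    rss = rss, n_obs = n, dof = dof, reduced_chi2 = chi2, adjusted_r2 = ar2,
    jacobian_condition = jac_cond, ill_conditioned = ill,
    se_reliable = !ill,
    n_starts = n_starts, n_starts_converged = length(near),
    seed = seed, weighting = wt$scheme, zero_tol = zero_tol,
    single_buffer = single_buffer, converged = TRUE,
    panel = panel, data = as.data.frame(dataset)
  ), class = "species_fit")
}

#' Restricted per-species fit
#'
#' Identical procedure to [fit_species_global()] with the Vmax of every
#' activity outside `keep` frozen at 0 and excluded from the
#' degrees-of-freedom accounting — e.g. asking whether the most highly
#' expressed transporters alone can account for the measured uptake.
#'
#' @inheritParams fit_species_global
#' @param keep Character vector of activity_ids to fit (non-empty
#'   subset of the panel).
#' @return A `species_fit`.
#' @export
fit_species_restricted <- function(dataset, panel, keep,
                                   weights = c("auto", "1/sd2", "none"),
                                   n_starts = 16L, zero_tol = 1e-4, seed = 1L,
                                   cond_threshold = 30) {
  if (missing(keep) || length(keep) == 0L) {
    stop("`keep` must name at least one activity", call. = FALSE)
  }
  fit_species_global(dataset, panel, keep = keep, weights = weights,
                     n_starts = n_starts, zero_tol = zero_tol, seed = seed,
                     cond_threshold = cond_threshold)
}

#' Compare a full and a restricted species fit
#'
#' Descriptive comparison of two nested fits on identical data: changes
#' in adjusted R-squared and reduced chi-square with parameter counts.
#' No automatic selection rule is applied; the verdict is a text
#' summary.
#'
#' @param full,restricted `species_fit` objects on the same dataset;
#'   `restricted`'s free activities must be a subset of `full`'s.
#' @return A `model_comparison` list with `delta_adjusted_r2` and
#'   `delta_reduced_chi2` (restricted minus full) and a `verdict`.
#' @export
compare_models <- function(full, restricted) {
  stopifnot(inherits(full, "species_fit"), inherits(restricted, "species_fit"))
  if (!isTRUE(all.equal(full$data, restricted$data))) {
    stop("fits were not performed on identical data", call. = FALSE)
  }
  if (!all(restricted$keep %in% full$keep)) {
    stop("restricted model's activities are not a subset of the full model's",
         call. = FALSE)
  }
  d_ar2 <- restricted$adjusted_r2 - full$adjusted_r2
  d_chi2 <- restricted$reduced_chi2 - full$reduced_chi2
  verdict <- sprintf(paste0(
    "full model: %d free parameters, reduced chi2 %.4g, adjusted R2 %.4f; ",
    "restricted model: %d free parameters, reduced chi2 %.4g, adjusted R2 %.4f. ",
    "Restricted-minus-full: delta reduced chi2 = %.4g, delta adjusted R2 = %.4g. ",
    "%s"),
    length(full$keep), full$reduced_chi2, full$adjusted_r2,
    length(restricted$keep), restricted$reduced_chi2, restricted$adjusted_r2,
    d_chi2, d_ar2,
    if (is.finite(d_ar2) && d_ar2 >= 0)
      "The restricted model fits at least as well per degree of freedom."
    else
      "The full model fits better per degree of freedom.")
  structure(list(full = full, restricted = restricted,
                 delta_adjusted_r2 = d_ar2, delta_reduced_chi2 = d_chi2,
                 verdict = verdict),
            class = "model_comparison")
}

#' Per-activity contribution curves
#'
#' Evaluates each activity's fitted Michaelis-Menten curve over a
#' concentration grid (default 0-1 mM, the assayed range) in the given
#' buffer, plus their sum, which equals the panel forward model at
#' every grid point.
#'
#' @param fit A converged `species_fit`.
#' @param panel Panel to evaluate (defaults to the fit's own).
#' @param s_grid Concentration grid, mM.
#' @param buffer `"sodium"` or `"sodium_free"`.
#' @return data.frame: `s_mM`, one column per activity, `total`.
#' @export
species_contribution_curves <- function(fit, panel = fit$panel,
                                        s_grid = seq(0, 1, length.out = 201),
                                        buffer = "sodium") {
  stopifnot(inherits(fit, "species_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  buffer <- buffer_condition(buffer)
  active <- activity_is_active(panel, buffer)
  curves <- sapply(seq_len(nrow(panel)), function(i) {
    if (active[i]) mm_rate(fit$vmax[[panel$activity_id[i]]], panel$km_mM[i], s_grid)
    else rep(0, length(s_grid))
  })
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1L)
  colnames(curves) <- panel$activity_id
  out <- data.frame(s_mM = s_grid, curves, check.names = FALSE)
  out$total <- rowSums(curves)
  out
}

#' @export
print.species_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Species fit: NOT converged (", x$n_starts_converged, "/", x$n_starts,
        " starts)\n", sep = "")
    return(invisible(x))
  }
  cat("Per-species Vmax fit (", length(x$keep), " free of ",
      length(x$vmax), " activities; seed ", x$seed, ")\n", sep = "")
  tab <- data.frame(vmax = x$vmax, se = x$se,
                    zero = names(x$vmax) %in% x$zero_activity_set,
                    frozen = names(x$vmax) %in% x$frozen)
  print(format(tab, digits = 4))
  cat(sprintf("RSS %.4g on %d DOF; reduced chi2 %.4g; adjusted R2 %.4f (%s weights)\n",
              x$rss, x$dof, x$reduced_chi2, x$adjusted_r2, x$weighting))
  cat(sprintf("Jacobian condition %.3g%s; %d/%d starts at the optimum\n",
              x$jacobian_condition,
              if (x$ill_conditioned) " [ILL-CONDITIONED: SEs unreliable]" else "",
              x$n_starts_converged, x$n_starts))
  if (length(x$zero_activity_set)) {
    cat("Zero-activity set:", paste(x$zero_activity_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison\n", x$verdict, "\n")
  invisible(x)
}
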