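# Aggregate (pooled) Michaelis-Menten fits: a single (Vmax, Km) pair
# fitted to one uptake curve by weighted nonlinear least squares.

#' Fit the Michaelis-Menten equation to one uptake curve
#'
#' Weighted nonlinear least squares of `V = Vmax * S / (Km + S)` by
#' Levenberg-Marquardt with non-negativity bounds. Observations are
#' weighted `1/sd^2` when every SD is positive, else unweighted.
#' Standard errors come from the local curvature (Jacobian) at the
#' optimum, scaled by the reduced chi-square. Degenerate inputs (fewer
#' than 3 distinct concentrations, flat or all-zero rates) yield a
#' result flagged as non-converged rather than an error, so batch runs
#' survive bad curves.
#'
#' @param observations An `uptake_dataset` restricted to one curve, or
#'   any data.frame with columns `concentration_mM`, `rate_mean` and
#'   optionally `rate_sd`. For a difference curve from
#'   [na_dependent_difference()], columns `difference`/`sd` are accepted.
#' @param weights Weighting scheme: `"auto"` (default), `"1/sd2"`, or
#'   `"none"`.
#' @return An `aggregate_mm_fit` list: `vmax_hat`, `vmax_se`, `km_hat`,
#'   `km_se`, `rss`, `n_obs`, `dof`, `reduced_chi2`, `adjusted_r2`,
#'   `converged`, `km_identifiable`, `weighting`, `message`.
#' @export
fit_aggregate_mm <- function(observations, weights = c("auto", "1/sd2", "none")) {
  weights <- match.arg(weights)
  df <- as.data.frame(observations)
  if (!is.null(df$difference) && is.null(df$rate_mean)) {
    df$rate_mean <- df$difference
    if (!is.null(df$sd)) df$rate_sd <- df$sd
  }
  if (is.null(df$rate_sd)) df$rate_sd <- NA_real_
  stopifnot(!is.null(df$concentration_mM), !is.null(df$rate_mean))
  if (any(!is.finite(df$rate_mean))) {
    stop("non-finite uptake rates in input", call. = FALSE)
  }

  failed <- function(msg) {
    structure(list(vmax_hat = NA_real_, vmax_se = NA_real_, km_hat = NA_real_,
                   km_se = NA_real_, rss = NA_real_, n_obs = nrow(df),
                   dof = NA_integer_, reduced_chi2 = NA_real_,
                   adjusted_r2 = NA_real_, converged = FALSE,
                   km_identifiable = FALSE, weighting = weights, message = msg),
              class = "aggregate_mm_fit")
  }

  s <- df$concentration_mM
  y <- df$rate_mean
  if (length(unique(s)) < 3L) {
    return(failed("fewer than 3 distinct concentrations; Vmax and Km not identifiable"))
  }
  wt <- tryCatch(fit_weights(df$rate_sd, weights), error = function(e) NULL)
  if (is.null(wt)) return(failed("invalid SDs for requested weighting scheme"))
  w <- wt$w

  if (all(y == 0)) {
    res <- failed("all rates zero: vmax -> 0, Km not identifiable")
    res$vmax_hat <- 0
    res$rss <- 0
    return(res)
  }
  if (diff(range(y)) == 0) {
    return(failed("rates constant across concentrations; Km not identifiable"))
  }

  # starts: plateau level and half-saturating concentration
  vmax0 <- max(y)
  km0 <- {
    above <- which(y >= vmax0 / 2)
    if (length(above)) max(min(s[above]), min(s[s > 0])) else stats::median(s[s > 0])
  }
  resid_fn <- function(p) sqrt(w) * (y - mm_rate(p[1], p[2], s))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(vmax = vmax0, km = km0), fn = resid_fn,
                       lower = c(0, 1e-12),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(failed(if (is.null(fit)) "optimizer error" else fit$message))
  }
  p <- fit$par
  rss <- sum(resid_fn(p)^2)
  n <- length(y)
  dof <- n - 2L
  chi2 <- reduced_chi2(rss, n, 2L)
  ar2 <- adjusted_r2(rss, weighted_tss(y, w), n, 2L)

  # curvature-based SEs
  J <- cbind(sqrt(w) * s / (p[2] + s),
             -sqrt(w) * p[1] * s / (p[2] + s)^2)
  cov <- chi2 * pseudo_inverse(crossprod(J))
  se <- sqrt(pmax(diag(cov), 0))

  structure(list(vmax_hat = unname(p[1]), vmax_se = se[1],
                 km_hat = unname(p[2]), km_se = se[2],
                 rss = rss, n_obs = n, dof = dof, reduced_chi2 = chi2,
                 adjusted_r2 = ar2, converged = TRUE, km_identifiable = TRUE,
                 weighting = wt$scheme, message = "converged"),
            class = "aggregate_mm_fit")
}

#' @export
print.aggregate_mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit:",
      if (x$converged) "converged" else paste("NOT converged:", x$message), "\n")
  if (x$converged) {
    cat(sprintf("  Vmax = %.4g +/- %.3g\n  Km   = %.4g +/- %.3g mM\n",
                x$vmax_hat, x$vmax_se, x$km_hat, x$km_se))
    cat(sprintf("  RSS %.4g on %d DOF; reduced chi2 %.4g; adj R2 %.4f (%s weights)\n",
                x$rss, x$dof, x$reduced_chi2, x$adjusted_r2, x$weighting))
  }
  invisible(x)
}
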