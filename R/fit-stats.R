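# Goodness-of-fit statistics used as the fitting objective and for
# model comparison: reduced chi-square and DOF-adjusted R-squared.

#' Reduced chi-square
#'
#' The weighted residual sum of squares divided by the degrees of
#' freedom (number of observations minus free parameters).
#'
#' @param rss Weighted residual sum of squares.
#' @param n_obs Number of observations.
#' @param n_params Number of free parameters.
#' @return `rss / (n_obs - n_params)`.
#' @export
reduced_chi2 <- function(rss, n_obs, n_params) {
  dof <- n_obs - n_params
  if (dof <= 0) {
    stop("degrees of freedom must be positive (n_obs = ", n_obs,
         ", n_params = ", n_params, ")", call. = FALSE)
  }
  rss / dof
}

#' Adjusted R-squared
#'
#' Coefficient of determination penalized for model degrees of freedom:
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` with `R2 = 1 - rss/tss`.
#' Values closer to 1 indicate a better fit.
#'
#' @param rss Weighted residual sum of squares.
#' @param tss Weighted total sum of squares about the weighted mean.
#' @param n_obs Number of observations.
#' @param n_params Number of free parameters.
#' @return Adjusted R-squared, or `NA` (with a warning) when `tss` is 0.
#' @export
adjusted_r2 <- function(rss, tss, n_obs, n_params) {
  if (!is.finite(tss) || tss < 0) stop("`tss` must be finite and >= 0", call. = FALSE)
  if (tss == 0) {
    warning("total sum of squares is zero; adjusted R-squared undefined")
    return(NA_real_)
  }
  if (n_obs - n_params - 1 < 1) {
    stop("adjusted R-squared requires n_obs - n_params - 1 >= 1", call. = FALSE)
  }
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n_obs - 1) / (n_obs - n_params - 1)
}

# Weighted total sum of squares about the weighted mean.
weighted_tss <- function(y, w) {
  ybar <- sum(w * y) / sum(w)
  sum(w * (y - ybar)^2)
}

# Observation weights: 1/sd^2 when every SD is positive, else unweighted.
fit_weights <- function(sd, scheme = c("auto", "1/sd2", "none")) {
  scheme <- match.arg(scheme)
  use_sd <- switch(scheme,
                   auto = all(is.finite(sd)) && all(sd > 0),
                   `1/sd2` = TRUE,
                   none = FALSE)
  if (use_sd) {
    if (any(!is.finite(sd)) || any(sd <= 0)) {
      stop("1/sd^2 weighting requires all SDs finite and positive", call. = FALSE)
    }
    list(w = 1 / sd^2, scheme = "1/sd2")
  } else {
    list(w = rep(1, length(sd)), scheme = "none")
  }
}

# Moore-Penrose pseudoinverse via SVD (for curvature-based SEs of
# possibly ill-conditioned designs).
pseudo_inverse <- function(m, tol = .Machine$double.eps^0.5) {
  sv <- svd(m)
  pos <- sv$d > tol * max(sv$d, 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}
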