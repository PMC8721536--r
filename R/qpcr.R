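# qPCR expression arithmetic: primer efficiency from dilution-series
# slopes, the E >= 1.6 acceptance filter, and relative expression by
# the comparative CT methods (2^-dCT vs a reference gene, 2^-ddCT vs a
# baseline condition).

#' Construct a CT measurement
#'
#' Technical-replicate cycle-threshold values for one gene in one
#' culture condition.
#'
#' @param gene Gene symbol.
#' @param condition Condition label (e.g. media and day).
#' @param ct_values Numeric vector of technical-replicate CT values,
#'   each in (0, 45).
#' @param reference_gene Reference (housekeeping) gene symbol, default
#'   `"HPRT"`.
#' @return A `ct_measurement` object.
#' @export
ct_measurement <- function(gene, condition, ct_values, reference_gene = "HPRT") {
  if (length(ct_values) < 1L || any(!is.finite(ct_values)) ||
      any(ct_values <= 0) || any(ct_values >= 45)) {
    stop("`ct_values` must be >= 1 finite values in (0, 45)", call. = FALSE)
  }
  structure(list(gene = gene, condition = condition,
                 ct_values = as.numeric(ct_values),
                 ct_mean = mean(ct_values), ct_sd = stats::sd(ct_values),
                 reference_gene = reference_gene),
            class = "ct_measurement")
}

#' Primer efficiency from a dilution series
#'
#' Ordinary least-squares regression of CT on log10 template input; the
#' efficiency is `E = 10^(-1/m) - 1` where `m` is the slope. Note that
#' under this formula perfect per-cycle doubling gives E = 1, so the
#' conventional acceptance bound used with it (E >= 1.6, see
#' [filter_primers()]) implies super-perfect amplification; the
#' discrepancy is documented rather than resolved, and the filter
#' threshold is configurable.
#'
#' @param series data.frame with columns `ng_per_reaction` (template
#'   input, ng) and `ct` (mean CT), or two vectors via `ng` and `ct`.
#' @param ng,ct Alternative vector interface.
#' @return A `dilution_series` list: `slope`, `intercept`, `efficiency`,
#'   `r_squared`, `points`.
#' @examples
#' s <- simulate_dilution_series(amplification = 2, noise_sd = 0)
#' primer_efficiency(s)$efficiency  # 1.0 for perfect doubling
#' @export
primer_efficiency <- function(series = NULL, ng = series$ng_per_reaction,
                              ct = series$ct) {
  if (is.null(ng) || is.null(ct)) {
    stop("supply a data.frame with ng_per_reaction and ct, or `ng` and `ct` vectors",
         call. = FALSE)
  }
  if (length(ng) != length(ct) || length(ng) < 3L) {
    stop("a dilution series needs >= 3 (input, CT) points", call. = FALSE)
  }
  if (any(!is.finite(ng)) || any(ng <= 0) || any(!is.finite(ct))) {
    stop("template inputs must be positive and CTs finite", call. = FALSE)
  }
  lx <- log10(ng)
  if (diff(range(lx)) < 1) {
    stop("dilution series must span at least one log10 of template input",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ lx)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m >= -sqrt(.Machine$double.eps)) {
    stop("dilution-series slope must be finite and negative (got ", format(m), ")",
         call. = FALSE)
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ct - mean(ct))^2)
  structure(list(slope = m, intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / m) - 1,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 points = data.frame(ng_per_reaction = ng, ct = ct)),
            class = "dilution_series")
}

#' Partition primers by efficiency threshold
#'
#' Primers with efficiency at or above the threshold are accepted for
#' further experiments; the bound is inclusive.
#'
#' @param efficiencies Named numeric vector of per-primer efficiencies
#'   (or a list of `dilution_series`).
#' @param threshold Acceptance bound, default 1.6.
#' @return List with character vectors `accepted` and `rejected` (and
#'   the efficiencies used).
#' @export
filter_primers <- function(efficiencies, threshold = 1.6) {
  if (is.list(efficiencies) && !is.data.frame(efficiencies)) {
    efficiencies <- vapply(efficiencies, function(x) {
      if (inherits(x, "dilution_series")) x$efficiency else as.numeric(x)
    }, numeric(1))
  }
  if (length(efficiencies) == 0L) {
    return(list(accepted = character(0), rejected = character(0),
                efficiencies = numeric(0), threshold = threshold))
  }
  if (any(!is.finite(efficiencies))) {
    stop("all efficiencies must be finite", call. = FALSE)
  }
  nm <- names(efficiencies) %||% as.character(seq_along(efficiencies))
  keep <- efficiencies >= threshold
  list(accepted = nm[keep], rejected = nm[!keep],
       efficiencies = stats::setNames(efficiencies, nm), threshold = threshold)
}

#' Relative expression by the comparative CT method
#'
#' `dCT = mean CT(target) - mean CT(reference)`; relative expression is
#' `2^-dCT`. Target and reference must come from the same condition.
#'
#' @param target,reference `ct_measurement` objects for the target and
#'   the reference (housekeeping) gene in the same condition.
#' @return An `expression_result` list: `gene`, `condition`,
#'   `reference_gene`, `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(target, reference) {
  stopifnot(inherits(target, "ct_measurement"), inherits(reference, "ct_measurement"))
  if (!identical(target$condition, reference$condition)) {
    stop("target and reference CTs are from different conditions (",
         target$condition, " vs ", reference$condition, ")", call. = FALSE)
  }
  dct <- target$ct_mean - reference$ct_mean
  structure(list(gene = target$gene, condition = target$condition,
                 reference_gene = reference$gene,
                 delta_ct = dct, rel_expr = 2^(-dct),
                 delta_delta_ct = NA_real_, fold_change = NA_real_),
            class = "expression_result")
}

#' Fold change by the ddCT method
#'
#' `ddCT = dCT(target condition) - dCT(baseline condition)`; the fold
#' change is `2^-ddCT`, and the baseline condition against itself gives
#' exactly 1.
#'
#' @param target_expr,baseline_expr `expression_result` objects for the
#'   same gene and reference gene in two conditions.
#' @return `target_expr` with `delta_delta_ct` and `fold_change` filled.
#' @export
fold_change <- function(target_expr, baseline_expr) {
  stopifnot(inherits(target_expr, "expression_result"),
            inherits(baseline_expr, "expression_result"))
  if (!identical(target_expr$gene, baseline_expr$gene)) {
    stop("fold change requires the same gene (", target_expr$gene, " vs ",
         baseline_expr$gene, ")", call. = FALSE)
  }
  if (!identical(target_expr$reference_gene, baseline_expr$reference_gene)) {
    stop("fold change requires the same reference gene", call. = FALSE)
  }
  ddct <- target_expr$delta_ct - baseline_expr$delta_ct
  target_expr$delta_delta_ct <- ddct
  target_expr$fold_change <- 2^(-ddct)
  target_expr
}

#' Expression ratio between two genes in one condition
#'
#' How many-fold more abundant gene A's transcript is than gene B's:
#' `rel_expr(A) / rel_expr(B) = 2^(dCT_B - dCT_A)`.
#'
#' @param gene_a,gene_b `expression_result` objects from the same
#'   condition and reference gene.
#' @return Numeric ratio.
#' @export
expression_ratio <- function(gene_a, gene_b) {
  stopifnot(inherits(gene_a, "expression_result"),
            inherits(gene_b, "expression_result"))
  if (!identical(gene_a$condition, gene_b$condition)) {
    stop("expression ratio requires the same condition", call. = FALSE)
  }
  if (!identical(gene_a$reference_gene, gene_b$reference_gene)) {
    stop("expression ratio requires the same reference gene", call. = FALSE)
  }
  2^(gene_b$delta_ct - gene_a$delta_ct)
}

#' Expression table from a long CT table
#'
#' Table-level driver over [relative_expression()] and [fold_change()]:
#' averages technical replicates, computes dCT and 2^-dCT per
#' gene/condition against the reference gene, and, when a baseline
#' condition is given, ddCT and 2^-ddCT against it.
#'
#' @param ct_table data.frame with columns `gene`, `condition`,
#'   `replicate`, `ct`, and optionally logicals `is_reference`,
#'   `is_control`. Control rows (no-template / -RT) are excluded from
#'   quantification; see [qc_controls()].
#' @param reference_gene Reference gene symbol (default `"HPRT"`); rows
#'   with `is_reference = TRUE` must agree with it if both are present.
#' @param baseline Optional baseline condition label for fold changes.
#' @return data.frame: `gene`, `condition`, `delta_ct`, `rel_expr`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
qpcr_expression <- function(ct_table, reference_gene = "HPRT", baseline = NULL) {
  df <- as.data.frame(ct_table, stringsAsFactors = FALSE)
  needed <- c("gene", "condition", "ct")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("CT table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(df$is_control)) df <- df[!as.logical(df$is_control), , drop = FALSE]
  if (!reference_gene %in% df$gene) {
    stop("reference gene ", reference_gene, " absent from CT table", call. = FALSE)
  }
  conditions <- unique(df$condition)
  rows <- list()
  for (cond in conditions) {
    sub <- df[df$condition == cond, , drop = FALSE]
    ref_ct <- sub$ct[sub$gene == reference_gene]
    if (length(ref_ct) == 0L) {
      stop("reference gene ", reference_gene, " has no CT values in condition ",
           sQuote(cond), call. = FALSE)
    }
    ref <- ct_measurement(reference_gene, cond, ref_ct, reference_gene)
    for (g in setdiff(unique(sub$gene), reference_gene)) {
      tgt <- ct_measurement(g, cond, sub$ct[sub$gene == g], reference_gene)
      rows[[length(rows) + 1L]] <- relative_expression(tgt, ref)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r$gene, condition = r$condition, delta_ct = r$delta_ct,
               rel_expr = r$rel_expr, delta_delta_ct = NA_real_,
               fold_change = NA_real_, stringsAsFactors = FALSE)
  }))
  if (!is.null(baseline)) {
    if (!baseline %in% out$condition) {
      stop("baseline condition ", sQuote(baseline), " absent from CT table",
           call. = FALSE)
    }
    for (i in seq_len(nrow(out))) {
      base_dct <- out$delta_ct[out$gene == out$gene[i] & out$condition == baseline]
      if (length(base_dct) == 1L) {
        out$delta_delta_ct[i] <- out$delta_ct[i] - base_dct
        out$fold_change[i] <- 2^(-out$delta_delta_ct[i])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' QC of -RT and no-template control rows
#'
#' Control reactions must show no amplification: their CT must be
#' absent (`NA`) or at/above the "undetermined" cutoff.
#'
#' @param ct_table data.frame with at least `gene`, `condition`, `ct`
#'   and logical `is_control`.
#' @param max_ct CT at or above which a reaction counts as
#'   undetermined (default 40).
#' @return List: `pass` (logical), `failures` (offending control rows).
#' @export
qc_controls <- function(ct_table, max_ct = 40) {
  df <- as.data.frame(ct_table, stringsAsFactors = FALSE)
  if (is.null(df$is_control)) {
    return(list(pass = TRUE, failures = df[0, , drop = FALSE]))
  }
  ctrl <- df[as.logical(df$is_control), , drop = FALSE]
  bad <- ctrl[!is.na(ctrl$ct) & ctrl$ct < max_ct, , drop = FALSE]
  rownames(bad) <- NULL
  list(pass = nrow(bad) == 0L, failures = bad)
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series: slope %.4f, efficiency E = %.4f (R2 %.4f, %d points)\n",
              x$slope, x$efficiency, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("%s [%s] vs %s: dCT = %.3f, 2^-dCT = %.4g",
              x$gene, x$condition, x$reference_gene, x$delta_ct, x$rel_expr))
  if (!is.na(x$fold_change)) {
    cat(sprintf("; ddCT = %.3f, fold = %.4g", x$delta_delta_ct, x$fold_change))
  }
  cat("\n")
  invisible(x)
}
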