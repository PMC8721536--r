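# Uptake-dataset container, normalization to the 300 uM sodium-buffer
# reference, and the sodium-dependent difference curve.

#' Construct an uptake dataset
#'
#' Replicate-aggregated uptake observations: mean rate, replicate SD and
#' replicate count per (concentration, buffer) pair. Raw rates are in
#' pmol/(min*cm2) of filter area; after [normalize_dataset()] rates are
#' dimensionless relative to the sodium-buffer rate at the reference
#' concentration.
#'
#' @param data data.frame with columns `concentration_mM`, `buffer`
#'   (`"sodium"`/`"sodium_free"`), `rate_mean`, `rate_sd`, `n`.
#' @param normalized Logical; is the dataset already on the normalized
#'   scale?
#' @param reference_mM Reference concentration for normalization, mM
#'   (default 0.3, i.e. 300 uM).
#' @param units Unit string for the rates.
#' @return An `uptake_dataset` (a classed data.frame with metadata
#'   attributes).
#' @export
uptake_dataset <- function(data, normalized = FALSE, reference_mM = 0.3,
                           units = if (normalized) "normalized" else "pmol/(min.cm2)") {
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  needed <- c("concentration_mM", "buffer", "rate_mean", "rate_sd", "n")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("uptake data lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("uptake dataset must be non-empty", call. = FALSE)
  bad <- which(!df$buffer %in% BUFFER_LEVELS)
  if (length(bad)) {
    stop("invalid buffer label in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$buffer[bad]), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$concentration_mM) | df$concentration_mM < 0)
  if (length(bad)) {
    stop("invalid concentration_mM (must be finite, >= 0) in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$rate_sd) | df$rate_sd < 0)
  if (length(bad)) {
    stop("invalid rate_sd (must be finite, >= 0) in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$n) | df$n < 1)
  if (length(bad)) {
    stop("invalid replicate count n (must be >= 1) in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- df[, needed]
  rownames(df) <- NULL
  structure(df,
            normalized = normalized,
            reference_mM = reference_mM,
            units = units,
            norm_factor = attr(data, "norm_factor"),
            raw_units = attr(data, "raw_units"),
            class = c("uptake_dataset", "data.frame"))
}

is_normalized <- function(dataset) isTRUE(attr(dataset, "normalized"))

#' Normalize an uptake dataset to the sodium-buffer reference rate
#'
#' Divides every mean rate and SD (both buffers) by the sodium-buffer
#' mean rate at the reference concentration, the shared-reference
#' convention that preserves the ordering total >= sodium-independent.
#' The scale factor and original units are recorded so the raw scale can
#' be recovered with [denormalize_dataset()].
#'
#' @param dataset An `uptake_dataset`, not yet normalized.
#' @param reference_mM Reference concentration, mM; defaults to the
#'   dataset's `reference_mM` attribute (0.3 mM = 300 uM).
#' @return A normalized `uptake_dataset`.
#' @export
normalize_dataset <- function(dataset, reference_mM = attr(dataset, "reference_mM")) {
  stopifnot(inherits(dataset, "uptake_dataset"))
  if (is_normalized(dataset)) {
    stop("dataset is already normalized; refusing to normalize twice", call. = FALSE)
  }
  ref_rows <- dataset$buffer == "sodium" & dataset$concentration_mM == reference_mM
  if (!any(ref_rows)) {
    stop("no sodium-buffer observation at the reference concentration (",
         reference_mM, " mM); cannot normalize", call. = FALSE)
  }
  ref_rate <- mean(dataset$rate_mean[ref_rows])
  if (!is.finite(ref_rate) || ref_rate <= 0) {
    stop("reference rate at ", reference_mM, " mM is ", ref_rate,
         "; must be positive to normalize", call. = FALSE)
  }
  out <- as.data.frame(dataset)
  out$rate_mean <- out$rate_mean / ref_rate
  out$rate_sd <- out$rate_sd / ref_rate
  out <- uptake_dataset(out, normalized = TRUE, reference_mM = reference_mM,
                        units = "normalized")
  attr(out, "norm_factor") <- ref_rate
  attr(out, "raw_units") <- attr(dataset, "units")
  out
}

#' Undo normalization using the stored scale factor
#'
#' @param dataset A normalized `uptake_dataset` produced by
#'   [normalize_dataset()].
#' @return The dataset on its original raw scale.
#' @export
denormalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "uptake_dataset"))
  if (!is_normalized(dataset)) stop("dataset is not normalized", call. = FALSE)
  f <- attr(dataset, "norm_factor")
  if (is.null(f)) stop("no stored normalization factor; cannot denormalize",
                       call. = FALSE)
  out <- as.data.frame(dataset)
  out$rate_mean <- out$rate_mean * f
  out$rate_sd <- out$rate_sd * f
  uptake_dataset(out, normalized = FALSE,
                 reference_mM = attr(dataset, "reference_mM"),
                 units = attr(dataset, "raw_units") %||% "pmol/(min.cm2)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_buffer <- function(dataset, buffer) {
  buffer <- buffer_condition(buffer)
  out <- dataset[dataset$buffer == buffer, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sodium-dependent uptake as a difference curve
#'
#' The conventional decomposition: sodium-dependent transport at each
#' concentration is total (sodium buffer) minus sodium-independent
#' (sodium-free buffer) uptake, with SDs propagated in quadrature.
#' Negative differences, which can arise from noise, are retained and
#' flagged rather than clipped, so downstream fits are not biased.
#'
#' @param total `uptake_dataset` (or subset) holding sodium-buffer rows.
#'   If `na_free` is missing and `total` contains both buffers it is
#'   split internally.
#' @param na_free `uptake_dataset` holding sodium-free rows.
#' @return data.frame with `concentration_mM`, `difference`, `sd`
#'   (quadrature-propagated), and logical `negative`.
#' @export
na_dependent_difference <- function(total, na_free = NULL) {
  stopifnot(inherits(total, "uptake_dataset"))
  if (is.null(na_free)) {
    na_free <- subset_buffer(total, "sodium_free")
    total <- subset_buffer(total, "sodium")
  } else {
    stopifnot(inherits(na_free, "uptake_dataset"))
    if (!identical(is_normalized(total), is_normalized(na_free))) {
      stop("both datasets must be on the same (raw or normalized) scale",
           call. = FALSE)
    }
    total <- subset_buffer(total, "sodium")
    na_free <- subset_buffer(na_free, "sodium_free")
  }
  shared <- intersect(total$concentration_mM, na_free$concentration_mM)
  if (length(shared) == 0L) {
    stop("no shared concentrations between buffers; cannot form difference curve",
         call. = FALSE)
  }
  shared <- sort(shared)
  t_idx <- match(shared, total$concentration_mM)
  f_idx <- match(shared, na_free$concentration_mM)
  diff <- total$rate_mean[t_idx] - na_free$rate_mean[f_idx]
  sd <- sqrt(total$rate_sd[t_idx]^2 + na_free$rate_sd[f_idx]^2)
  data.frame(concentration_mM = shared, difference = diff, sd = sd,
             negative = diff < 0)
}

#' @export
print.uptake_dataset <- function(x, ...) {
  cat("Uptake dataset:", nrow(x), "observations;",
      if (is_normalized(x)) "normalized" else "raw",
      paste0("[", attr(x, "units"), "]"),
      "; reference", attr(x, "reference_mM"), "mM\n")
  print.data.frame(x, ...)
  invisible(x)
}
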