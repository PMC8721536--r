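# File formats and pipeline drivers. On disk, concentrations are in uM
# (matching assay descriptions); internally everything is mM. Buffer
# labels use the fixed vocabulary {sodium, sodium_free}, with common
# aliases accepted on read and normalized on write.

BUFFER_ALIASES <- c(
  "sodium" = "sodium", "+na" = "sodium", "+na+" = "sodium", "na" = "sodium",
  "total" = "sodium",
  "sodium_free" = "sodium_free", "sodiumfree" = "sodium_free",
  "nafree" = "sodium_free", "na+free" = "sodium_free", "na_free" = "sodium_free",
  "-na" = "sodium_free", "nmdg" = "sodium_free")

normalize_buffer_labels <- function(x) {
  key <- tolower(gsub("[ ^]", "", x))
  out <- unname(BUFFER_ALIASES[key])
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("unrecognized buffer label in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(x[bad]), collapse = ", "),
         " (expected sodium/sodium_free or a known alias)", call. = FALSE)
  }
  out
}

# Polynomial rolling hash over the JSON form of a configuration;
# fingerprints runs in outputs (not cryptographic).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

pkg_version <- function() as.character(utils::packageVersion("aatdeconv"))

#' Read / write a transporter panel file
#'
#' CSV or JSON (by extension) with fields `activity_id`, `gene_id`,
#' `alias`, `km_mM`, `sodium_dependent`, `vmax_literature_nmol_h`,
#' `mechanism`. `read_panel("default")` returns the shipped default
#' panel.
#'
#' @param path File path, or `"default"`.
#' @return An `aat_panel`.
#' @export
read_panel <- function(path) {
  if (identical(path, "default")) return(default_panel())
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  candidate_panel(df)
}

#' @rdname read_panel
#' @param panel An `aat_panel` to write.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "aat_panel"))
  df <- as.data.frame(panel)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write an uptake table
#'
#' CSV with header `concentration_uM, buffer, rate, sd, n`; a sidecar
#' `<path>.json` carries metadata (units, normalized flag,
#' reference_uM). Concentrations are converted to mM on read.
#'
#' @param path CSV path.
#' @return An `uptake_dataset`.
#' @export
read_uptake <- function(path) {
  if (!file.exists(path)) stop("uptake file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("concentration_uM", "buffer", "rate", "sd", "n")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("uptake CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  normalized <- isTRUE(meta$normalized)
  reference_mM <- (meta$reference_uM %||% 300) / 1000
  out <- data.frame(concentration_mM = df$concentration_uM / 1000,
                    buffer = normalize_buffer_labels(df$buffer),
                    rate_mean = df$rate, rate_sd = df$sd, n = df$n,
                    stringsAsFactors = FALSE)
  ds <- uptake_dataset(out, normalized = normalized, reference_mM = reference_mM,
                       units = meta$units %||%
                         if (normalized) "normalized" else "pmol/(min.cm2)")
  if (!is.null(meta$norm_factor)) attr(ds, "norm_factor") <- meta$norm_factor
  if (!is.null(meta$raw_units)) attr(ds, "raw_units") <- meta$raw_units
  ds
}

#' @rdname read_uptake
#' @param dataset An `uptake_dataset` to write.
#' @export
write_uptake <- function(dataset, path) {
  stopifnot(inherits(dataset, "uptake_dataset"))
  df <- data.frame(concentration_uM = dataset$concentration_mM * 1000,
                   buffer = dataset$buffer, rate = dataset$rate_mean,
                   sd = dataset$rate_sd, n = dataset$n)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(units = attr(dataset, "units"),
               normalized = is_normalized(dataset),
               reference_uM = attr(dataset, "reference_mM") * 1000,
               format_version = "1.0",
               package_version = pkg_version())
  if (!is.null(attr(dataset, "norm_factor"))) {
    meta$norm_factor <- attr(dataset, "norm_factor")
    meta$raw_units <- attr(dataset, "raw_units")
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a qPCR CT table
#'
#' CSV with columns `gene, condition, replicate, ct, is_reference,
#' is_control`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("CT table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("gene", "condition", "ct")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("CT table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_ct_table
#' @param ct_table data.frame to write.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE)
  invisible(path)
}

#' Read a primer dilution-series table
#'
#' CSV with columns `primer, ng_per_reaction, ct`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_dilution_series <- function(path) {
  if (!file.exists(path)) stop("dilution series not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("primer", "ng_per_reaction", "ct")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("dilution-series CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a species-fit result as JSON
#'
#' Stable-keyed JSON: a per-activity array of `{activity_id, vmax_hat,
#' se, zero_flag, frozen}` followed by fit statistics, seed, weighting
#' and the run fingerprint.
#'
#' @param fit A `species_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_species_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "species_fit"))
  per_activity <- lapply(names(fit$vmax), function(id) {
    list(activity_id = id,
         vmax_hat = unname(fit$vmax[[id]]),
         se = unname(fit$se[[id]]),
         zero_flag = id %in% fit$zero_activity_set,
         frozen = id %in% fit$frozen)
  })
  obj <- list(
    format_version = "1.0",
    package_version = pkg_version(),
    activities = per_activity,
    rss = fit$rss, dof = fit$dof, reduced_chi2 = fit$reduced_chi2,
    adjusted_r2 = fit$adjusted_r2,
    jacobian_condition = fit$jacobian_condition,
    ill_conditioned = fit$ill_conditioned,
    weighting = fit$weighting, seed = fit$seed,
    n_starts = fit$n_starts, n_starts_converged = fit$n_starts_converged,
    zero_activity_set = as.list(fit$zero_activity_set),
    single_buffer = fit$single_buffer)
  obj$config_hash <- config_hash(obj[c("weighting", "seed", "n_starts")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Write per-activity contribution curves as TSV
#'
#' @param curves data.frame from [species_contribution_curves()].
#' @param path Output path.
#' @param buffer Buffer the curves were evaluated in (recorded in a
#'   header comment).
#' @export
write_curves_tsv <- function(curves, path, buffer = "sodium") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# buffer=%s package_version=%s", buffer, pkg_version()), con)
  utils::write.table(curves, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate an uptake experiment to files
#'
#' Writes the uptake CSV (+ metadata sidecar) and the ground truth as a
#' separate sidecar JSON, so fitting code cannot accidentally read the
#' truth.
#'
#' @param out_dir Output directory (must exist).
#' @param truth `"default4"` or a named per-activity Vmax vector.
#' @param seed RNG seed.
#' @param quiet Suppress the log line.
#' @param ... Passed to [simulate_uptake()].
#' @return Paths of the written files, invisibly.
#' @export
run_simulate_uptake <- function(out_dir, truth = "default4", seed = 1L,
                                quiet = FALSE, ...) {
  if (!dir.exists(out_dir)) stop("output directory not found: ", out_dir,
                                 call. = FALSE)
  tv <- if (identical(truth, "default4")) default_truth() else truth
  sim <- simulate_uptake(true_vmax = tv, seed = seed, ...)
  data_path <- file.path(out_dir, "uptake.csv")
  truth_path <- file.path(out_dir, "uptake_truth.json")
  write_uptake(sim$dataset, data_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!quiet) {
    message("simulate-uptake: seed ", seed, ", ", nrow(sim$dataset),
            " rows -> ", data_path)
  }
  invisible(list(data = data_path, truth = truth_path))
}

#' Simulate a qPCR CT table to files
#'
#' @param out_dir Output directory.
#' @param true_rel_expr Named vector or genes x conditions matrix of
#'   relative expression ground truth.
#' @param seed RNG seed.
#' @param quiet Suppress the log line.
#' @param ... Passed to [simulate_ct_table()].
#' @return Paths of the written files, invisibly.
#' @export
run_simulate_qpcr <- function(out_dir, true_rel_expr, seed = 1L, quiet = FALSE,
                              ...) {
  if (!dir.exists(out_dir)) stop("output directory not found: ", out_dir,
                                 call. = FALSE)
  sim <- simulate_ct_table(true_rel_expr, seed = seed, ...)
  data_path <- file.path(out_dir, "ct_table.csv")
  truth_path <- file.path(out_dir, "ct_truth.json")
  write_ct_table(sim$ct_table, data_path)
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!quiet) {
    message("simulate-qpcr: seed ", seed, ", ", nrow(sim$ct_table),
            " rows -> ", data_path)
  }
  invisible(list(data = data_path, truth = truth_path))
}

#' Full uptake-deconvolution pipeline on files
#'
#' Reads an uptake CSV, normalizes it, fits the aggregate
#' Michaelis-Menten curves (total, sodium-independent, and the
#' sodium-dependent difference curve), runs the global per-species fit
#' (plus an optional restricted fit and comparison), and writes the
#' result JSON, contribution-curve TSV and a plain-text report.
#'
#' @param uptake_csv Input uptake CSV path.
#' @param out_dir Output directory.
#' @param panel Panel file path or `"default"`.
#' @param restrict Optional character vector of activity_ids for a
#'   restricted fit.
#' @param seed RNG seed for the multi-start optimizer.
#' @param n_starts Multi-start count.
#' @param weights Weighting scheme.
#' @param zero_tol Zero-activity threshold (relative).
#' @param quiet Suppress log lines.
#' @return Invisibly, a list with the fit objects and output paths.
#' @export
run_fit_species <- function(uptake_csv, out_dir, panel = "default",
                            restrict = NULL, seed = 1L, n_starts = 16L,
                            weights = "auto", zero_tol = 1e-4, quiet = FALSE) {
  if (!dir.exists(out_dir)) stop("output directory not found: ", out_dir,
                                 call. = FALSE)
  pan <- read_panel(panel)
  raw <- read_uptake(uptake_csv)
  ds <- if (is_normalized(raw)) raw else normalize_dataset(raw)

  total <- subset_buffer(ds, "sodium")
  nafree <- subset_buffer(ds, "sodium_free")
  agg <- list(total = fit_aggregate_mm(total, weights = weights))
  diff_curve <- NULL
  if (nrow(nafree) > 0L) {
    agg$na_independent <- fit_aggregate_mm(nafree, weights = weights)
    diff_curve <- na_dependent_difference(ds)
    agg$na_dependent <- fit_aggregate_mm(diff_curve, weights = weights)
  }

  fit <- fit_species_global(ds, pan, weights = weights, n_starts = n_starts,
                            zero_tol = zero_tol, seed = seed)
  restricted <- NULL
  comparison <- NULL
  if (!is.null(restrict)) {
    restricted <- fit_species_restricted(ds, pan, keep = restrict,
                                         weights = weights, n_starts = n_starts,
                                         zero_tol = zero_tol, seed = seed)
    comparison <- compare_models(fit, restricted)
  }

  fit_path <- file.path(out_dir, "species_fit.json")
  curves_path <- file.path(out_dir, "curves_sodium.tsv")
  report_path <- file.path(out_dir, "report.txt")
  write_species_fit_json(fit, fit_path)
  write_curves_tsv(species_contribution_curves(fit), curves_path, "sodium")

  report <- c(
    sprintf("aatdeconv %s species-fit report", pkg_version()),
    sprintf("input: %s; panel: %s; seed: %d; weights: %s", uptake_csv,
            if (is.character(panel)) panel else "custom", seed, fit$weighting),
    "", "Aggregate Michaelis-Menten fits:",
    vapply(names(agg), function(nm) {
      a <- agg[[nm]]
      if (a$converged)
        sprintf("  %-14s Vmax %.4g +/- %.3g, Km %.4g +/- %.3g mM (adj R2 %.4f)",
                nm, a$vmax_hat, a$vmax_se, a$km_hat, a$km_se, a$adjusted_r2)
      else sprintf("  %-14s not converged: %s", nm, a$message)
    }, character(1)),
    "", "Per-species global fit (normalized rate units):",
    vapply(names(fit$vmax), function(id) {
      sprintf("  %-10s Vmax %.4g +/- %.3g%s", id, fit$vmax[[id]], fit$se[[id]],
              if (id %in% fit$zero_activity_set) "  [zero activity]" else "")
    }, character(1)),
    sprintf("  RSS %.4g on %d DOF; reduced chi2 %.4g; adjusted R2 %.4f",
            fit$rss, fit$dof, fit$reduced_chi2, fit$adjusted_r2),
    sprintf("  zero-activity set: %s",
            paste(fit$zero_activity_set, collapse = ", ")))
  if (!is.null(comparison)) {
    report <- c(report, "", "Restricted-model comparison:",
                paste(" ", comparison$verdict))
  }
  writeLines(report, report_path)
  if (!quiet) message("fit-species: wrote ", fit_path)
  invisible(list(fit = fit, aggregate = agg, restricted = restricted,
                 comparison = comparison, difference_curve = diff_curve,
                 paths = list(fit = fit_path, curves = curves_path,
                              report = report_path)))
}

#' qPCR expression pipeline on files
#'
#' Reads a CT table CSV, runs control QC and the comparative CT
#' arithmetic, and writes a long-format expression table.
#'
#' @param ct_csv Input CT table CSV.
#' @param out Output CSV path.
#' @param baseline Optional baseline condition for fold changes.
#' @param reference_gene Reference gene, default `"HPRT"`.
#' @param max_ct Undetermined-CT cutoff for control QC.
#' @param quiet Suppress log lines.
#' @return Invisibly, the expression table (with QC result attached as
#'   attribute `qc`).
#' @export
run_qpcr <- function(ct_csv, out, baseline = NULL, reference_gene = "HPRT",
                     max_ct = 40, quiet = FALSE) {
  ct <- read_ct_table(ct_csv)
  qc <- qc_controls(ct, max_ct = max_ct)
  if (!qc$pass) {
    warning("QC failure: ", nrow(qc$failures),
            " control reaction(s) with detectable CT")
  }
  expr <- qpcr_expression(ct, reference_gene = reference_gene,
                          baseline = baseline)
  utils::write.csv(expr, out, row.names = FALSE)
  if (!quiet) message("qpcr: wrote ", nrow(expr), " rows -> ", out)
  attr(expr, "qc") <- qc
  invisible(expr)
}
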