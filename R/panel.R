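# Transporter registry and forward flux model: a panel of candidate
# SLC amino-acid transporter activities, each a plain Michaelis-Menten
# component with a fixed literature Km and a sodium-dependence gate.

BUFFER_LEVELS <- c("sodium", "sodium_free")

#' Validate a buffer condition label
#'
#' Uptake assays are run in sodium-containing buffer (all transporters
#' active; "total" uptake) or sodium-free buffer (NMDG replaces sodium;
#' only sodium-independent transporters active).
#'
#' @param buffer Character scalar, one of `"sodium"` or `"sodium_free"`.
#' @return The validated buffer label.
#' @export
buffer_condition <- function(buffer) {
  if (!is.character(buffer) || length(buffer) != 1L || !buffer %in% BUFFER_LEVELS) {
    stop("`buffer` must be one of ", paste(sQuote(BUFFER_LEVELS), collapse = ", "),
         call. = FALSE)
  }
  buffer
}

#' Construct a single transporter kinetic activity
#'
#' One Michaelis-Menten component of the flux model: an SLC amino-acid
#' transporter species (or one affinity component of a biphasic
#' transporter) with its substrate affinity and sodium dependence.
#'
#' @param activity_id Short unique label, e.g. `"LAT1"` or `"LAT4_low"`.
#' @param gene_id SLC gene symbol, e.g. `"SLC7A5"`.
#' @param km Michaelis constant for the substrate, mM. Must be positive.
#' @param sodium_dependent Logical; does transport require extracellular
#'   sodium?
#' @param mechanism One of `"symporter"`, `"antiporter"`, `"uniporter"`.
#' @param alias Display name (defaults to `activity_id`).
#' @param vmax_literature Optional literature maximal rate, nmol/h.
#'   Reference metadata only; never used as a fitting constraint.
#' @return An object of class `kinetic_activity`.
#' @examples
#' kinetic_activity("LAT1", "SLC7A5", km = 0.032, sodium_dependent = FALSE,
#'                  mechanism = "antiporter", vmax_literature = 0.162)
#' @export
kinetic_activity <- function(activity_id, gene_id, km, sodium_dependent,
                             mechanism = c("symporter", "antiporter", "uniporter"),
                             alias = activity_id, vmax_literature = NA_real_) {
  mechanism <- match.arg(mechanism)
  if (!is.character(activity_id) || length(activity_id) != 1L || !nzchar(activity_id)) {
    stop("`activity_id` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(km) || length(km) != 1L || !is.finite(km) || km <= 0) {
    stop("`km` must be a single finite positive value (mM); offending field: km",
         call. = FALSE)
  }
  if (!is.logical(sodium_dependent) || length(sodium_dependent) != 1L ||
      is.na(sodium_dependent)) {
    stop("`sodium_dependent` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(activity_id = activity_id, gene_id = gene_id, alias = alias,
         km = as.numeric(km), sodium_dependent = sodium_dependent,
         vmax_literature = as.numeric(vmax_literature), mechanism = mechanism),
    class = "kinetic_activity"
  )
}

#' Assemble a candidate panel of transporter activities
#'
#' @param activities A list of [kinetic_activity()] objects, or a
#'   data.frame with columns `activity_id`, `gene_id`, `alias`, `km_mM`,
#'   `sodium_dependent`, `vmax_literature_nmol_h`, `mechanism`.
#' @return An `aat_panel`: a data.frame with one row per activity.
#' @export
candidate_panel <- function(activities) {
  if (is.list(activities) && !is.data.frame(activities) &&
      length(activities) == 0L) {
    stop("a candidate panel must be non-empty", call. = FALSE)
  }
  if (is.data.frame(activities)) {
    df <- as.data.frame(activities, stringsAsFactors = FALSE)
    needed <- c("activity_id", "gene_id", "km_mM", "sodium_dependent", "mechanism")
    missing <- setdiff(needed, names(df))
    if (length(missing)) {
      stop("panel data.frame lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(df$alias)) df$alias <- df$activity_id
    if (is.null(df$vmax_literature_nmol_h)) df$vmax_literature_nmol_h <- NA_real_
  } else if (is.list(activities) &&
             all(vapply(activities, inherits, logical(1), "kinetic_activity"))) {
    df <- do.call(rbind, lapply(activities, function(a) {
      data.frame(activity_id = a$activity_id, gene_id = a$gene_id, alias = a$alias,
                 km_mM = a$km, sodium_dependent = a$sodium_dependent,
                 vmax_literature_nmol_h = a$vmax_literature,
                 mechanism = a$mechanism, stringsAsFactors = FALSE)
    }))
  } else {
    stop("`activities` must be a list of kinetic_activity objects or a data.frame",
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("a candidate panel must be non-empty", call. = FALSE)
  if (anyDuplicated(df$activity_id)) {
    stop("duplicate activity_id in panel: ",
         paste(unique(df$activity_id[duplicated(df$activity_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$km_mM)) || any(df$km_mM <= 0)) {
    stop("all Km values must be finite and positive; offending field: km_mM",
         call. = FALSE)
  }
  df$sodium_dependent <- as.logical(df$sodium_dependent)
  df <- df[, c("activity_id", "gene_id", "alias", "km_mM", "sodium_dependent",
               "vmax_literature_nmol_h", "mechanism")]
  rownames(df) <- NULL
  class(df) <- c("aat_panel", "data.frame")
  df
}

#' The default blood-brain barrier leucine transporter panel
#'
#' Eight kinetic activities over seven SLC genes with detectable
#' expression in the hCMEC/D3 brain endothelial model: the sodium
#' symporter B0AT2, the antiporters LAT1, b0,+AT, y+LAT1, y+LAT2 and
#' ASCT2, and the facilitative uniporter LAT4, whose biphasic leucine
#' kinetics contribute a high- and a low-affinity component
#' (`LAT4_high`, `LAT4_low`). Km values (mM) are fixed literature
#' affinities and are never refit; literature Vmax values (nmol/h) are
#' carried as reference metadata only.
#'
#' @return An `aat_panel` with 8 rows.
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  candidate_panel(list(
    kinetic_activity("B0AT2",     "SLC6A15", 0.160,  TRUE,  "symporter",
                     vmax_literature = NA_real_),
    kinetic_activity("LAT1",      "SLC7A5",  0.032,  FALSE, "antiporter",
                     vmax_literature = 0.162),
    kinetic_activity("b0+AT",     "SLC7A9",  1.1,    FALSE, "antiporter",
                     alias = "b0,+AT", vmax_literature = NA_real_),
    kinetic_activity("y+LAT1",    "SLC7A7",  0.0317, TRUE,  "antiporter",
                     vmax_literature = 0.38),
    kinetic_activity("y+LAT2",    "SLC7A6",  0.236,  TRUE,  "antiporter",
                     vmax_literature = 1.60),
    kinetic_activity("ASCT2",     "SLC1A5",  0.367,  TRUE,  "antiporter",
                     vmax_literature = 1.01),
    kinetic_activity("LAT4_high", "SLC43A2", 0.103,  FALSE, "uniporter",
                     alias = "LAT4_high", vmax_literature = 0.024),
    kinetic_activity("LAT4_low",  "SLC43A2", 3.73,   FALSE, "uniporter",
                     alias = "LAT4_low", vmax_literature = 3.52)
  ))
}

#' Michaelis-Menten transport rate
#'
#' `v = vmax * s / (km + s)`.
#'
#' @param vmax Maximal transport rate (any rate unit); must be >= 0.
#' @param km Michaelis constant, mM; must be > 0.
#' @param s Substrate concentration, mM; must be >= 0. Vectorized.
#' @return Transport rate(s), same unit as `vmax`.
#' @examples
#' mm_rate(vmax = 0.162, km = 0.032, s = 0.032)  # half-saturation
#' @export
mm_rate <- function(vmax, km, s) {
  if (!is.numeric(vmax) || any(!is.finite(vmax)) || any(vmax < 0)) {
    stop("invalid Michaelis-Menten input; offending field: vmax (must be finite, >= 0)",
         call. = FALSE)
  }
  if (!is.numeric(km) || any(!is.finite(km)) || any(km <= 0)) {
    stop("invalid Michaelis-Menten input; offending field: km (must be finite, > 0)",
         call. = FALSE)
  }
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("invalid Michaelis-Menten input; offending field: s (must be finite, >= 0)",
         call. = FALSE)
  }
  vmax * s / (km + s)
}

#' Is a transporter activity operative in a given buffer?
#'
#' All activities carry flux in sodium buffer; in sodium-free buffer
#' only sodium-independent activities do.
#'
#' @param activity A [kinetic_activity()] or an `aat_panel` (vectorized
#'   over its rows).
#' @param buffer `"sodium"` or `"sodium_free"`.
#' @return Logical (one element per activity).
#' @export
activity_is_active <- function(activity, buffer) {
  buffer <- buffer_condition(buffer)
  sodium_dep <- if (inherits(activity, "kinetic_activity")) {
    activity$sodium_dependent
  } else if (inherits(activity, "aat_panel") || is.data.frame(activity)) {
    activity$sodium_dependent
  } else {
    stop("`activity` must be a kinetic_activity or an aat_panel", call. = FALSE)
  }
  if (buffer == "sodium") rep(TRUE, length(sodium_dep)) else !sodium_dep
}

#' Total panel transport rate
#'
#' Forward model: the summed Michaelis-Menten flux of all activities
#' operative in the given buffer, each at its own fixed Km and a
#' supplied per-activity Vmax.
#'
#' @param panel An `aat_panel`.
#' @param vmax_vector Numeric vector of per-activity maximal rates, in
#'   panel order (names, if present, are checked against the panel).
#' @param s Substrate concentration, mM (vectorized).
#' @param buffer `"sodium"` or `"sodium_free"`.
#' @return Total rate(s), one per element of `s`.
#' @export
panel_rate <- function(panel, vmax_vector, s, buffer) {
  stopifnot(inherits(panel, "aat_panel"))
  buffer <- buffer_condition(buffer)
  if (length(vmax_vector) != nrow(panel)) {
    stop("`vmax_vector` has length ", length(vmax_vector),
         " but the panel has ", nrow(panel), " activities", call. = FALSE)
  }
  if (!is.null(names(vmax_vector)) &&
      !identical(names(vmax_vector), panel$activity_id)) {
    stop("names of `vmax_vector` do not match panel activity_ids (in order)",
         call. = FALSE)
  }
  if (any(!is.finite(vmax_vector)) || any(vmax_vector < 0)) {
    stop("invalid input; offending field: vmax_vector (must be finite, >= 0)",
         call. = FALSE)
  }
  active <- activity_is_active(panel, buffer)
  # rows: concentrations, cols: activities
  rates <- outer(s, seq_len(nrow(panel)), function(si, i) {
    mm_rate(1, panel$km_mM[i], si)
  })
  as.numeric(rates %*% (vmax_vector * active))
}

#' @export
print.aat_panel <- function(x, ...) {
  cat("Candidate transporter panel:", nrow(x), "kinetic activities,",
      length(unique(x$gene_id)), "genes\n")
  print.data.frame(x, ...)
  invisible(x)
}
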