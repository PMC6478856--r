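#' Radiocarbon database handling
#'
#' A `date_set` wraps one table of radiocarbon determinations together with a
#' provenance log that records, per laboratory ID, every quarantine or
#' rejection decision with a machine-readable reason code.  The accounting
#' invariant `retained + rejected + quarantined = input rows` holds at every
#' stage.
#'
#' @name date_set
NULL

.regions <- c("Cantabrian", "Ebro", "Atlantic", "Mediterranean", "Interior")
.site_types <- c("open_air", "cave_rockshelter", "unknown")
.material_classes <- c("short_lived", "long_lived", "aggregate", "excluded_class")
.curve_classes <- c("atmospheric", "marine", "mixed")

.dataset_columns <- c("lab_id", "site_id", "site_name", "region", "latitude",
                      "longitude", "site_type", "material", "material_class",
                      "aggregate_consistent", "c14_age_bp", "c14_error",
                      "d13c", "curve_class", "context_id")
.mandatory_columns <- c("lab_id", "site_id", "region", "site_type",
                        "material_class", "c14_age_bp", "c14_error",
                        "curve_class")

.new_date_set <- function(dates, log, input_n) {
  structure(list(dates = dates, log = log, input_n = input_n),
            class = "date_set")
}

.log_entry <- function(lab_id, stage, action, reason) {
  data.frame(lab_id = as.character(lab_id), stage = stage, action = action,
             reason = reason, stringsAsFactors = FALSE)
}

#' @export
print.date_set <- function(x, ...) {
  cat("<date_set> ", nrow(x$dates), " retained of ", x$input_n,
      " input determinations\n", sep = "")
  if (nrow(x$log)) {
    tab <- table(x$log$reason)
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Load a radiocarbon database from CSV
#'
#' Expects one row per determination with the documented column schema
#' (`lab_id, site_id, site_name, region, latitude, longitude, site_type,
#' material, material_class, aggregate_consistent, c14_age_bp, c14_error,
#' d13c, curve_class, context_id`).  Rows with unparseable mandatory fields
#' or out-of-vocabulary enum values are quarantined with a reason code
#' rather than dropped silently.
#'
#' @param path CSV path, or a data.frame with the same columns.
#' @return A `date_set`.
#' @export
load_dataset <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.mandatory_columns, names(df))
  if (length(missing_cols))
    stop_schema(paste0("dataset is missing mandatory columns: ",
                       paste(missing_cols, collapse = ", ")))
  for (col in setdiff(.dataset_columns, names(df))) df[[col]] <- NA
  df <- df[.dataset_columns]
  df$lab_id <- as.character(df$lab_id)
  df$c14_age_bp <- suppressWarnings(as.numeric(df$c14_age_bp))
  df$c14_error <- suppressWarnings(as.numeric(df$c14_error))
  df$d13c <- suppressWarnings(as.numeric(df$d13c))
  df$aggregate_consistent <- as.logical(df$aggregate_consistent)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, code) ifelse(is.na(reason) & bad, code, reason)
  reason <- flag(is.na(df$lab_id) | !nzchar(df$lab_id), "missing_lab_id")
  reason <- flag(is.na(df$c14_age_bp), "missing_age")
  reason <- flag(is.na(df$c14_error) | df$c14_error <= 0, "missing_error")
  reason <- flag(!(df$region %in% .regions), "unknown_region")
  reason <- flag(!(df$site_type %in% .site_types), "unknown_site_type")
  reason <- flag(!(df$material_class %in% .material_classes), "unknown_material_class")
  reason <- flag(!(df$curve_class %in% .curve_classes), "unknown_curve_class")

  bad <- !is.na(reason)
  log <- if (any(bad))
    .log_entry(df$lab_id[bad], "load", "quarantined", reason[bad])
  else .log_entry(character(), character(), character(), character())
  .new_date_set(df[!bad, , drop = FALSE], log, nrow(df))
}

#' Filter a radiocarbon database
#'
#' Applies the study's quality filters: laboratory errors must be strictly
#' below `max_error` years; excluded material classes (bulk sediment, land
#' snail carbonate and the like, coded `excluded_class`) are removed; and
#' multi-sample aggregates are retained only when flagged stratigraphically
#' consistent.  Every rejection is logged with one of the closed reason codes
#' `error_too_large`, `excluded_material`, `inconsistent_aggregate`.
#'
#' @param ds a `date_set`.
#' @param max_error strict upper bound on the lab error, years.
#' @param excluded_classes material classes to drop.
#' @return The filtered `date_set` (provenance log extended).
#' @export
filter_dates <- function(ds, max_error = 200,
                         excluded_classes = "excluded_class") {
  stopifnot(inherits(ds, "date_set"))
  if (max_error <= 0) stop_value("max_error must be positive")
  df <- ds$dates
  reason <- rep(NA_character_, nrow(df))
  reason[df$c14_error >= max_error] <- "error_too_large"
  reason[is.na(reason) & df$material_class %in% excluded_classes] <- "excluded_material"
  reason[is.na(reason) & df$material_class == "aggregate" &
           !(df$aggregate_consistent %in% TRUE)] <- "inconsistent_aggregate"
  bad <- !is.na(reason)
  log <- rbind(ds$log,
               if (any(bad)) .log_entry(df$lab_id[bad], "filter", "rejected",
                                        reason[bad]))
  .new_date_set(df[!bad, , drop = FALSE], log, ds$input_n)
}

#' Bin the dates of one site
#'
#' Groups near-contemporaneous uncalibrated determinations from a single
#' site into bins so that oversampled occupations do not dominate the summed
#' probability distribution.  The default rule is single-linkage clustering
#' on the uncalibrated age axis: ages are sorted and a new bin starts
#' whenever the gap to the previous age exceeds `bin_width` (a gap exactly
#' equal to the width keeps linking).  `method = "fixed_window"` instead
#' cuts absolute windows of `bin_width` years.
#'
#' @param ages uncalibrated 14C ages of one site's dates.
#' @param bin_width bin width in 14C years.
#' @param method `"single_linkage"` (default) or `"fixed_window"`.
#' @return Integer bin indices (1-based, in input order).
#' @export
bin_ages <- function(ages, bin_width = 200,
                     method = c("single_linkage", "fixed_window")) {
  method <- match.arg(method)
  if (bin_width <= 0) stop_value("bin_width must be positive")
  if (length(ages) == 0L) return(integer())
  if (method == "fixed_window") {
    idx <- floor(ages / bin_width)
    return(match(idx, sort(unique(idx))))
  }
  o <- order(ages)
  gaps <- c(0, diff(ages[o]))
  bins_sorted <- cumsum(gaps > bin_width) + 1L
  bins <- integer(length(ages))
  bins[o] <- bins_sorted
  bins
}

#' Assign site bins across a whole database
#'
#' Applies [bin_ages()] per site and attaches a `bin_id` column
#' (`<site_id>_<k>`) to the retained dates.
#'
#' @param ds a `date_set`.
#' @param bin_width bin width in 14C years.
#' @param method passed to [bin_ages()].
#' @return The `date_set` with a `bin_id` column added.
#' @export
assign_bins <- function(ds, bin_width = 200,
                        method = c("single_linkage", "fixed_window")) {
  stopifnot(inherits(ds, "date_set"))
  method <- match.arg(method)
  df <- ds$dates
  df$bin_id <- NA_character_
  for (s in unique(df$site_id)) {
    i <- which(df$site_id == s)
    b <- bin_ages(df$c14_age_bp[i], bin_width, method)
    df$bin_id[i] <- paste(s, b, sep = "_")
  }
  ds$dates <- df
  attr(ds, "bin_width") <- bin_width
  ds
}

#' Pool same-context determinations
#'
#' Replaces each group of statistically equivalent determinations from the
#' same archaeological context (equal `site_id` and `context_id`) by its
#' Ward-Wilson pooled date, so one repeatedly dated event does not count
#' several times inside a bin.  Groups failing the chi-squared equivalence
#' test, and groups mixing calibration-curve classes (pooling across curves
#' is undefined), are left as individual dates with a logged warning.
#'
#' @param ds a `date_set`.
#' @param alpha significance level for the equivalence test.
#' @return The `date_set` after pooling; its size never increases.
#' @export
apply_combinations <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "date_set"))
  df <- ds$dates
  log <- ds$log
  has_ctx <- !is.na(df$context_id) & nzchar(as.character(df$context_id))
  key <- paste(df$site_id, df$context_id, sep = "\r")
  drop <- logical(nrow(df))
  for (k in unique(key[has_ctx])) {
    i <- which(key == k & has_ctx)
    if (length(i) < 2L) next
    if (length(unique(df$curve_class[i])) > 1L) {
      log <- rbind(log, .log_entry(df$lab_id[i], "combine", "kept",
                                   "mixed_curve_class_not_combined"))
      next
    }
    cmb <- combine_equivalent(df$c14_age_bp[i], df$c14_error[i], alpha)
    if (cmb$passed) {
      keep <- i[1L]
      df$lab_id[keep] <- paste(df$lab_id[i], collapse = "+")
      df$c14_age_bp[keep] <- cmb$pooled_age
      df$c14_error[keep] <- cmb$pooled_error
      df$d13c[keep] <- mean(df$d13c[i], na.rm = TRUE)
      drop[i[-1L]] <- TRUE
      log <- rbind(log, .log_entry(df$lab_id[keep], "combine", "combined",
                                   "pooled_equivalent_context"))
    } else {
      log <- rbind(log, .log_entry(df$lab_id[i], "combine", "kept",
                                   "combination_failed_chi_sq"))
    }
  }
  .new_date_set(df[!drop, , drop = FALSE], log, ds$input_n)
}

#' Write a date set and its provenance log
#'
#' @param ds a `date_set`.
#' @param path CSV path for the retained dates.
#' @param log_path optional CSV path for the provenance log.
#' @export
write_dataset <- function(ds, path, log_path = NULL) {
  utils::write.csv(ds$dates, path, row.names = FALSE)
  if (!is.null(log_path))
    utils::write.csv(ds$log, log_path, row.names = FALSE)
  invisible(path)
}
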