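# Glue between the database layer and the SPD layer: calibrate every retained
# date on its appropriate curve, group densities into site bins, and build the
# per-component and composite SPDs.

#' Curve set for calibrating a database
#'
#' Bundles the curves and settings needed to calibrate a mixed database:
#' dates flagged `atmospheric` use the atmospheric curve; `marine` dates use
#' the marine curve shifted by the local reservoir offset; `mixed` dates use
#' a mixed curve whose marine fraction comes from the sample's delta-13C.
#'
#' @param atmospheric atmospheric [cal_curve()].
#' @param marine optional marine [cal_curve()]; required if the database
#'   contains marine or mixed dates.
#' @param reservoir a [reservoir_spec()].
#' @param d13c_endpoints `c(terrestrial, marine)` endpoints for
#'   [marine_fraction_from_d13c()].
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(atmospheric, marine = NULL,
                      reservoir = reservoir_spec(),
                      d13c_endpoints = c(-21, -12)) {
  structure(list(atmospheric = atmospheric, marine = marine,
                 reservoir = reservoir, d13c_endpoints = d13c_endpoints),
            class = "curve_set")
}

.curve_for_date <- function(curves, curve_class, d13c) {
  if (curve_class == "atmospheric" || is.null(curves$marine))
    return(curves$atmospheric)
  if (curve_class == "marine")
    return(mix_curves(curves$atmospheric, curves$marine, 1, curves$reservoir))
  f <- if (is.na(d13c)) 0.5 else
    marine_fraction_from_d13c(d13c, curves$d13c_endpoints[1L],
                              curves$d13c_endpoints[2L])
  mix_curves(curves$atmospheric, curves$marine, f, curves$reservoir)
}

#' Calibrate a binned database into per-bin densities
#'
#' @param ds a `date_set` with bins assigned (see [assign_bins()]).
#' @param curves a [curve_set()] or a single [cal_curve()].
#' @return A list with `bins` (named list: bin id -> list of `cal_density`),
#'   `components` (bin id -> site-type component) and `log` rows for any
#'   dates that could not be calibrated.
#' @export
calibrate_dataset <- function(ds, curves) {
  stopifnot(inherits(ds, "date_set"))
  if (inherits(curves, "cal_curve")) curves <- curve_set(curves)
  df <- ds$dates
  if (is.null(df$bin_id)) stop_value("assign_bins() must be run first")
  bins <- list()
  comp <- character()
  bad <- .log_entry(character(), character(), character(), character())
  for (i in seq_len(nrow(df))) {
    cc <- .curve_for_date(curves, df$curve_class[i], df$d13c[i])
    d <- tryCatch(calibrate(df$c14_age_bp[i], df$c14_error[i], cc,
                            source_id = df$lab_id[i]),
                  paleodem_range_error = function(e) NULL)
    if (is.null(d)) {
      bad <- rbind(bad, .log_entry(df$lab_id[i], "calibrate", "rejected",
                                   "uncalibratable"))
      next
    }
    b <- df$bin_id[i]
    bins[[b]] <- c(bins[[b]], list(d))
    comp[b] <- switch(df$site_type[i],
                      open_air = "open_air",
                      cave_rockshelter = "closed_site",
                      "unclassified")
  }
  list(bins = bins, components = comp, log = bad)
}

#' Build component and composite SPDs from calibrated bins
#'
#' Sums bins per site-type component, applies the taphonomic correction to
#' the open-air component and the optional scaling correction to all
#' components, and composes the final SPD.
#'
#' @param cal result of [calibrate_dataset()].
#' @param window build window `c(t_max, t_min)` cal BP.
#' @param taphonomy a [taphonomic_model()], or `NULL` to skip.
#' @param scaling a [scaling_model()] (disabled by default).
#' @return A list of SPDs: `open_air`, `closed_site`, `unclassified` (any may
#'   be `NULL`) and `composite`.
#' @export
build_spd_components <- function(cal, window, taphonomy = taphonomic_model(),
                                 scaling = scaling_model()) {
  out <- list(open_air = NULL, closed_site = NULL, unclassified = NULL)
  for (cmp in names(out)) {
    ids <- names(cal$bins)[cal$components[names(cal$bins)] == cmp]
    if (length(ids) == 0L) next
    s <- sum_probabilities(cal$bins[ids], window, component = cmp)
    if (cmp == "open_air" && !is.null(taphonomy))
      s <- taphonomic_correct(s, taphonomy)
    s <- scaling_correct(s, scaling)
    out[[cmp]] <- s
  }
  out$composite <- compose_final(out$open_air, out$closed_site,
                                 out$unclassified)
  out
}
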