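#' Summed probability distributions
#'
#' An `spd` holds a per-year summed probability density over a calendar
#' window, used as a relative population-size proxy.  Within each site bin
#' the member densities are averaged (so each bin, not each date, carries
#' unit weight against oversampling); the SPD is the sum over bins.  The raw
#' density therefore integrates to the number of bins (up to support
#' truncation outside the window); [normalize_spd()] rescales to unit mass.
#'
#' @param cal_bp ascending calendar grid, 1-year step.
#' @param density per-year summed probability.
#' @param n_dates,n_bins bookkeeping counts.
#' @param component one of `"open_air"`, `"closed_site"`, `"unclassified"`,
#'   `"composite"`.
#' @param normalized whether `density` has been rescaled to unit mass.
#' @return An object of class `spd`.
#' @export
spd_curve <- function(cal_bp, density, n_dates = NA_integer_,
                      n_bins = NA_integer_, component = "composite",
                      normalized = FALSE) {
  if (length(cal_bp) != length(density))
    stop_value("cal_bp and density lengths differ")
  if (any(density < 0)) stop_value("SPD density must be non-negative")
  structure(list(cal_bp = as.numeric(cal_bp), density = as.numeric(density),
                 n_dates = n_dates, n_bins = n_bins, component = component,
                 window = c(max(cal_bp), min(cal_bp)), normalized = normalized),
            class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat("<spd> component=", x$component, ", window ", x$window[1], "-",
      x$window[2], " cal BP, ", x$n_bins, " bins / ", x$n_dates, " dates",
      if (x$normalized) ", normalized", "\n", sep = "")
  invisible(x)
}

#' @export
plot.spd <- function(x, ..., xlab = "cal BP", ylab = "summed probability") {
  graphics::plot(x$cal_bp, x$density, type = "l", xlim = rev(range(x$cal_bp)),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Sum calibrated bins into an SPD
#'
#' @param bins a list of bins; each bin is a list of `cal_density` members
#'   (see [calibrate()]).
#' @param window calendar window `c(t_max, t_min)` cal BP.
#' @param component component label for the result.
#' @param normalize if `TRUE`, rescale the summed curve to unit mass over the
#'   window; the default keeps the raw scale (total mass = number of bins up
#'   to truncation).
#' @return An [spd_curve()] on the 1-year grid spanning `window`.
#' @export
sum_probabilities <- function(bins, window, component = "composite",
                              normalize = FALSE) {
  if (length(bins) == 0L)
    stop_empty("no bins to sum: empty SPD")
  grid <- seq(min(window), max(window))
  acc <- numeric(length(grid))
  n_dates <- 0L
  for (bin in bins) {
    bin_acc <- numeric(length(grid))
    for (d in bin) {
      i <- match(d$cal_bp, grid)
      ok <- !is.na(i)
      bin_acc[i[ok]] <- bin_acc[i[ok]] + d$mass[ok]
      n_dates <- n_dates + 1L
    }
    acc <- acc + bin_acc / length(bin)
  }
  out <- spd_curve(grid, acc, n_dates = n_dates, n_bins = length(bins),
                   component = component)
  if (normalize) normalize_spd(out) else out
}

#' Rescale an SPD to unit mass
#' @param spd an [spd_curve()].
#' @return The SPD with `density` summing to 1.
#' @export
normalize_spd <- function(spd) {
  tot <- sum(spd$density)
  if (tot <= 0) stop_empty("cannot normalize an all-zero SPD")
  spd$density <- spd$density / tot
  spd$normalized <- TRUE
  spd
}

#' Taphonomic survival model
#'
#' Age-dependent loss of open-air archaeological deposits is modelled by the
#' survival function \eqn{s(t) = a (t + b)^c} with \eqn{c < 0}, so older
#' deposits survive at a lower rate.  The defaults are the global fit from
#' the taphonomy literature; all three constants are configurable.
#'
#' @param a scale.
#' @param b calendar offset, years.
#' @param c exponent (negative).
#' @return An object of class `taphonomic_model` with a `survival(t)` closure.
#' @export
taphonomic_model <- function(a = 5.726442e6, b = 2176.4, c = -1.3925309) {
  if (c >= 0) stop_model("taphonomic exponent c must be negative")
  if (a <= 0) stop_model("taphonomic scale a must be positive")
  structure(list(a = a, b = b, c = c,
                 survival = function(t) a * (t + b)^c),
            class = "taphonomic_model")
}

#' Correct an open-air SPD for taphonomic loss
#'
#' Divides the density by the survival function and rescales the result back
#' to the input's raw mass; the correction factor increases strictly with
#' calendar age, re-inflating the older part of the record.
#'
#' @param spd an open-air [spd_curve()].
#' @param model a [taphonomic_model()].
#' @return The corrected SPD.
#' @export
taphonomic_correct <- function(spd, model = taphonomic_model()) {
  if (!identical(spd$component, "open_air"))
    stop_value("taphonomic correction applies to the open-air component only")
  s <- model$survival(spd$cal_bp)
  if (any(!is.finite(s) | s <= 0))
    stop_model("taphonomic survival is non-positive inside the window")
  d <- spd$density / s
  tot_in <- sum(spd$density)
  if (sum(d) > 0) d <- d * tot_in / sum(d)
  spd$density <- d
  spd
}

#' Energy-consumption scaling model
#'
#' Optional non-linear scaling adjustment between the rate of anthropogenic
#' carbon deposition (what the SPD measures) and population size:
#' `density^(1/beta)`, renormalised.  Disabled by default, matching the
#' modelling choice of keeping the proxy on the raw deposition scale.
#'
#' @param beta scaling exponent (> 0).
#' @param enabled whether the correction is applied.
#' @return An object of class `scaling_model`.
#' @export
scaling_model <- function(beta = 1, enabled = FALSE) {
  if (beta <= 0) stop_model("scaling beta must be positive")
  structure(list(beta = beta, enabled = enabled), class = "scaling_model")
}

#' Apply the scaling correction to an SPD
#'
#' @param spd an [spd_curve()].
#' @param model a [scaling_model()].  Identity when disabled or `beta = 1`.
#' @return The (possibly) corrected SPD.
#' @export
scaling_correct <- function(spd, model = scaling_model()) {
  if (!model$enabled || model$beta == 1) return(spd)
  tot_in <- sum(spd$density)
  d <- spd$density^(1 / model$beta)
  if (sum(d) > 0 && tot_in > 0) d <- d * tot_in / sum(d)
  spd$density <- d
  spd
}

#' Compose the final SPD from site-type components
#'
#' Pointwise sum of the open-air (taphonomically corrected), cave/rockshelter
#' and unclassified components, trimmed to the requested window.
#'
#' @param spd_open,spd_closed,spd_unclassified component SPDs on a shared
#'   grid; any of them may be `NULL`.
#' @param window calendar window `c(t_max, t_min)`.
#' @return A composite [spd_curve()].
#' @export
compose_final <- function(spd_open = NULL, spd_closed = NULL,
                          spd_unclassified = NULL, window = NULL) {
  parts <- Filter(Negate(is.null), list(spd_open, spd_closed, spd_unclassified))
  if (length(parts) == 0L) stop_empty("no components to compose")
  grid <- parts[[1L]]$cal_bp
  for (p in parts)
    if (!identical(p$cal_bp, grid))
      stop_alignment("component SPDs are not on a shared calendar grid")
  acc <- Reduce(`+`, lapply(parts, `[[`, "density"))
  out <- spd_curve(grid, acc,
                   n_dates = sum(vapply(parts, `[[`, 0L, "n_dates")),
                   n_bins = sum(vapply(parts, `[[`, 0L, "n_bins")),
                   component = "composite")
  if (!is.null(window)) out <- trim_window(out, window)
  out
}

#' Trim an SPD to an analysis window
#'
#' Drops densities outside the range without renormalising (the model fitting
#' downstream is scale-free).  The analysis window must lie inside the build
#' window: the edge-effect guard is enforced, not advisory.
#'
#' @param spd an [spd_curve()].
#' @param analysis_range `c(t_max, t_min)` cal BP, inside the SPD's window.
#' @return The trimmed SPD.
#' @export
trim_window <- function(spd, analysis_range) {
  lo <- min(analysis_range); hi <- max(analysis_range)
  if (lo < min(spd$cal_bp) || hi > max(spd$cal_bp))
    stop_range("analysis window extends outside the SPD's build window")
  keep <- spd$cal_bp >= lo & spd$cal_bp <= hi
  if (!any(keep)) stop_empty("trim produced an empty SPD")
  spd$cal_bp <- spd$cal_bp[keep]
  spd$density <- spd$density[keep]
  spd$window <- c(hi, lo)
  spd
}

#' Write an SPD to CSV
#' @param spd an [spd_curve()].
#' @param path output path; columns `cal_bp`, `density`, `component`.
#' @export
write_spd <- function(spd, path) {
  utils::write.csv(data.frame(cal_bp = spd$cal_bp, density = spd$density,
                              component = spd$component),
                   path, row.names = FALSE)
  invisible(path)
}
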