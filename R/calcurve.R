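#' Calibration curve objects
#'
#' A `cal_curve` is the translation layer between calendar time and
#' radiocarbon time: for every calendar year BP on a regular grid it stores
#' the expected conventional radiocarbon age (`c14_mean`) and its one-sigma
#' uncertainty (`c14_sigma`).  Curves are stored on an ascending 1-year
#' calendar grid regardless of the order they were supplied in, so all
#' downstream operations are invariant to storage order.
#'
#' @param cal_bp calendar years BP, strictly monotonic (ascending or
#'   descending; normalised to ascending on construction).
#' @param c14_mean radiocarbon years BP at each grid point.
#' @param c14_sigma one-sigma radiocarbon-age uncertainty at each grid point,
#'   in years.  Must be non-negative; zero is permitted for noiseless
#'   synthetic curves used in round-trip tests.
#' @param name curve label.
#' @param resolution grid step in calendar years (after interpolation).
#' @return An object of class `cal_curve`.
#' @seealso [read_calcurve()], [make_synthetic_curve()], [calibrate()]
#' @export
cal_curve <- function(cal_bp, c14_mean, c14_sigma, name = "curve",
                      resolution = 1) {
  if (length(cal_bp) < 2L)
    stop_format("calibration curve needs at least 2 grid points")
  d <- diff(cal_bp)
  if (all(d < 0)) {                       # descending: normalise
    o <- rev(seq_along(cal_bp))
    cal_bp <- cal_bp[o]; c14_mean <- c14_mean[o]; c14_sigma <- c14_sigma[o]
  } else if (!all(d > 0)) {
    stop_format("calendar grid of a calibration curve must be strictly monotonic")
  }
  if (anyNA(c14_mean) || anyNA(c14_sigma))
    stop_value("calibration curve contains missing values")
  if (any(c14_sigma < 0))
    stop_value("calibration curve sigma must be non-negative")
  structure(
    list(name = name, cal_bp = as.numeric(cal_bp),
         c14_mean = as.numeric(c14_mean), c14_sigma = as.numeric(c14_sigma),
         resolution = resolution),
    class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("<cal_curve> ", x$name, "\n", sep = "")
  cat("  calendar range: ", min(x$cal_bp), "-", max(x$cal_bp), " cal BP (",
      length(x$cal_bp), " points, step ", x$resolution, " yr)\n", sep = "")
  cat("  14C range: ", round(min(x$c14_mean)), "-", round(max(x$c14_mean)),
      " 14C yr BP\n", sep = "")
  invisible(x)
}

#' Read a calibration curve file
#'
#' Reads curves in the standard `.14c` dialect: `#`-prefixed header lines
#' followed by comma- or whitespace-separated columns starting with
#' (cal BP, 14C age BP, 14C error); any further columns are ignored.  The
#' curve is linearly interpolated onto a regular calendar grid spanning the
#' file's range.
#'
#' @param path path to a `.14c` file.
#' @param resolution target grid step in calendar years.  The default of one
#'   year matches the resolution at which breakpoints are scanned downstream.
#' @return A [cal_curve()].
#' @export
read_calcurve <- function(path, resolution = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_format(sprintf("no data rows in calibration curve file '%s'", path))
  sep <- if (grepl(",", lines[[1L]])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE, fill = TRUE)
  if (ncol(tab) < 3L)
    stop_format("calibration curve file must have at least 3 columns (cal BP, 14C age, error)")
  cal <- as.numeric(tab[[1L]]); mu <- as.numeric(tab[[2L]]); sg <- as.numeric(tab[[3L]])
  if (anyNA(cal) || anyNA(mu) || anyNA(sg))
    stop_format("non-numeric values in calibration curve file")
  d <- diff(cal)
  if (!(all(d > 0) || all(d < 0)))
    stop_format("calendar column of calibration curve file is not strictly monotonic")
  if (any(sg <= 0))
    stop_value("calibration curve file contains non-positive sigma")
  grid <- seq(min(cal), max(cal), by = resolution)
  cal_curve(grid,
            stats::approx(cal, mu, xout = grid)$y,
            stats::approx(cal, sg, xout = grid)$y,
            name = basename(path), resolution = resolution)
}

#' Write a calibration curve file
#'
#' Writes the `.14c` dialect read by [read_calcurve()] (comma-separated,
#' descending calendar age, `#` header).
#'
#' @param curve a [cal_curve()].
#' @param path output path.
#' @export
write_calcurve <- function(curve, path) {
  o <- order(curve$cal_bp, decreasing = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", curve$name),
               "# cal BP, 14C age BP, 14C error"), con)
  writeLines(sprintf("%s,%s,%s",
                     format(curve$cal_bp[o], trim = TRUE, scientific = FALSE),
                     format(curve$c14_mean[o], trim = TRUE, scientific = FALSE),
                     format(curve$c14_sigma[o], trim = TRUE, scientific = FALSE)),
             con)
  invisible(path)
}

#' Marine reservoir offset specification
#'
#' Local offset (Delta-R) of a region's marine reservoir age from the global
#' marine calibration curve, with its uncertainty.
#'
#' @param delta_r mean offset in 14C years.
#' @param delta_r_sigma one-sigma uncertainty of the offset (>= 0).
#' @param region_label free-text label.
#' @return An object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(delta_r = 0, delta_r_sigma = 0, region_label = "") {
  if (delta_r_sigma < 0) stop_value("delta_r_sigma must be non-negative")
  structure(list(delta_r = delta_r, delta_r_sigma = delta_r_sigma,
                 region_label = region_label),
            class = "reservoir_spec")
}

#' Mix atmospheric and marine calibration curves
#'
#' Builds the mixed marine-terrestrial curve used to calibrate samples (for
#' example human bone collagen) whose carbon derives partly from the marine
#' reservoir.  On the shared calendar grid,
#' \deqn{\mu_{mix} = (1-f)\,\mu_{atm} + f\,(\mu_{mar} + \Delta R)}
#' \deqn{\sigma_{mix}^2 = ((1-f)\sigma_{atm})^2 + (f\sigma_{mar})^2 +
#'   (f\,\sigma_{\Delta R})^2}
#'
#' @param atm atmospheric [cal_curve()].
#' @param marine marine [cal_curve()].
#' @param f_marine marine diet fraction in `[0, 1]`.
#' @param reservoir a [reservoir_spec()].
#' @return A [cal_curve()] on the intersection of the two calendar ranges.
#' @export
mix_curves <- function(atm, marine, f_marine, reservoir = reservoir_spec()) {
  if (f_marine < 0 || f_marine > 1)
    stop_value("f_marine must be in [0, 1]")
  lo <- max(min(atm$cal_bp), min(marine$cal_bp))
  hi <- min(max(atm$cal_bp), max(marine$cal_bp))
  if (lo > hi)
    stop_coverage("atmospheric and marine curves have disjoint calendar ranges")
  ia <- which(atm$cal_bp >= lo & atm$cal_bp <= hi)
  im <- match(atm$cal_bp[ia], marine$cal_bp)
  if (anyNA(im))
    stop_alignment("curve grids do not share calendar points on the overlap")
  f <- f_marine
  mu <- (1 - f) * atm$c14_mean[ia] + f * (marine$c14_mean[im] + reservoir$delta_r)
  sg <- sqrt(((1 - f) * atm$c14_sigma[ia])^2 +
             (f * marine$c14_sigma[im])^2 +
             (f * reservoir$delta_r_sigma)^2)
  cal_curve(atm$cal_bp[ia], mu, sg,
            name = sprintf("mixed(%s,%s,f=%.3f)", atm$name, marine$name, f),
            resolution = atm$resolution)
}

#' Marine diet fraction from a stable-isotope value
#'
#' Linear interpolation of the marine carbon fraction between a fully
#' terrestrial and a fully marine delta-13C endpoint, clamped to `[0, 1]`.
#' Endpoint defaults (-21 permil terrestrial, -12 permil marine) follow
#' common marine-diet interpolation practice and are configurable.
#'
#' @param d13c delta-13C value(s) in permil.
#' @param terrestrial_end delta-13C of a fully terrestrial diet.
#' @param marine_end delta-13C of a fully marine diet.
#' @return Fraction(s) in `[0, 1]`.
#' @export
marine_fraction_from_d13c <- function(d13c, terrestrial_end = -21,
                                      marine_end = -12) {
  if (terrestrial_end == marine_end)
    stop_config("d13c endpoints must differ")
  if (terrestrial_end > marine_end)
    stop_config("terrestrial d13c endpoint must be below the marine endpoint")
  pmin(1, pmax(0, (d13c - terrestrial_end) / (marine_end - terrestrial_end)))
}

# linear interpolation of curve mean/sigma at (possibly non-grid) calendar ages
.curve_at <- function(curve, cal_age) {
  list(mu = stats::approx(curve$cal_bp, curve$c14_mean, xout = cal_age)$y,
       sigma = stats::approx(curve$cal_bp, curve$c14_sigma, xout = cal_age)$y)
}

#' Back-calibrate calendar ages to simulated radiocarbon ages
#'
#' Maps calendar ages to simulated radiocarbon determinations through the
#' curve: the curve mean at that age plus Gaussian noise with the curve's
#' one-sigma uncertainty.  This is the forward simulation step used by the
#' bootstrap and by null-model simulation; it consumes the current RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param cal_age calendar age(s) BP, inside the curve range.
#' @param curve a [cal_curve()].
#' @return Simulated 14C age(s) BP.
#' @export
back_calibrate <- function(cal_age, curve) {
  if (any(cal_age < min(curve$cal_bp) | cal_age > max(curve$cal_bp)))
    stop_range("calendar age outside calibration curve range")
  at <- .curve_at(curve, cal_age)
  at$mu + stats::rnorm(length(cal_age), 0, at$sigma)
}
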