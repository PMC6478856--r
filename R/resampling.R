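#' SPD ensembles
#'
#' An `spd_ensemble` is a set of simulated or bootstrapped SPDs on one
#' calendar grid, summarised by the pointwise median and a percentile
#' confidence band.  The default level of 95.4 (the two-sigma convention of
#' the calibration literature) uses the 2.3 and 97.7 pointwise percentiles.
#'
#' @param cal_bp shared calendar grid.
#' @param members matrix of member curves, one row per member.
#' @param ci_level band level in percent.
#' @param kind free-text label (`"bootstrap"`, `"null"`, `"subsample"`).
#' @param seed seed the ensemble was generated from (bookkeeping).
#' @return An object of class `spd_ensemble` with `median`, `lower`, `upper`.
#' @export
spd_ensemble <- function(cal_bp, members, ci_level = 95.4, kind = "ensemble",
                         seed = NA_integer_) {
  if (nrow(members) < 2L) stop_value("an ensemble needs at least 2 members")
  if (ncol(members) != length(cal_bp))
    stop_alignment("member curves and grid have different lengths")
  probs <- c(0.5 - ci_level / 200, 0.5, 0.5 + ci_level / 200)
  qs <- apply(members, 2L, stats::quantile, probs = probs, names = FALSE)
  structure(list(cal_bp = as.numeric(cal_bp), members = members,
                 lower = qs[1L, ], median_curve = qs[2L, ], upper = qs[3L, ],
                 ci_level = ci_level, kind = kind, seed = seed),
            class = "spd_ensemble")
}

#' @export
print.spd_ensemble <- function(x, ...) {
  cat("<spd_ensemble> ", nrow(x$members), " ", x$kind, " members, ",
      x$ci_level, "% band, window ", max(x$cal_bp), "-", min(x$cal_bp),
      " cal BP\n", sep = "")
  invisible(x)
}

#' @export
plot.spd_ensemble <- function(x, observed = NULL, ...,
                              xlab = "cal BP", ylab = "summed probability") {
  graphics::plot(x$cal_bp, x$median_curve, type = "n",
                 ylim = range(x$lower, x$upper,
                              if (!is.null(observed)) observed$density),
                 xlim = rev(range(x$cal_bp)), xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$cal_bp, rev(x$cal_bp)), c(x$lower, rev(x$upper)),
                    col = grDevices::grey(0.85), border = NA)
  graphics::lines(x$cal_bp, x$median_curve, lwd = 2)
  if (!is.null(observed))
    graphics::lines(observed$cal_bp, observed$density, col = "red")
  invisible(x)
}

#' Ensemble median as an SPD
#' @param ensemble an [spd_ensemble()].
#' @return An [spd_curve()] holding the pointwise median (the population
#'   proxy).
#' @export
ensemble_median <- function(ensemble) {
  spd_curve(ensemble$cal_bp, ensemble$median_curve, component = "composite",
            normalized = TRUE)
}

# One bootstrap / null-simulation iteration: draw calendar ages from a target
# density, push them through the curve and back, and sum.  Returns the
# window-restricted, unit-mass SPD vector.
.simulate_spd_once <- function(n, grid, prob, errors, curve, window_idx,
                               marine = NULL) {
  ages <- sample(grid, n, replace = TRUE, prob = prob)
  errs <- if (length(errors) == 1L) rep(errors, n) else
    sample(errors, n, replace = TRUE)
  if (is.null(marine)) {
    c14 <- back_calibrate(ages, curve)
    v <- .calibrate_sum(c14, errs, curve, window_idx)
  } else {
    is_mar <- stats::runif(n) < marine$proportion
    v <- numeric(length(window_idx))
    if (any(!is_mar)) {
      c14 <- back_calibrate(ages[!is_mar], curve)
      v <- v + .calibrate_sum(c14, errs[!is_mar], curve, window_idx)
    }
    if (any(is_mar)) {
      c14 <- back_calibrate(ages[is_mar], marine$curve)
      v <- v + .calibrate_sum(c14, errs[is_mar], marine$curve, window_idx)
    }
  }
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Bootstrap an SPD
#'
#' Quantifies the uncertainty the calibration process and laboratory errors
#' contribute to an SPD.  Each iteration resamples `n_bins` calendar ages
#' from the observed curve (inverse-CDF sampling), back-calibrates each
#' through the curve with curve noise, attaches a laboratory error drawn
#' with replacement from the empirical error pool, recalibrates, sums and
#' normalises.  Fully reproducible given `seed`.
#'
#' @param spd the observed [spd_curve()].
#' @param errors empirical pool of laboratory errors.
#' @param curve the [cal_curve()] used for back- and re-calibration.
#' @param n_iter number of bootstrap iterations (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param ci_level band level in percent.
#' @param n number of dates per iteration; defaults to the SPD's bin count
#'   (bins are the unit of evidence after anti-oversampling binning).
#' @return An [spd_ensemble()] of unit-mass member curves.
#' @export
bootstrap_spd <- function(spd, errors, curve, n_iter = 1000, seed = NULL,
                          ci_level = 95.4, n = spd$n_bins) {
  if (n_iter < 2L) stop_value("n_iter must be at least 2")
  if (length(errors) == 0L) stop_value("empty laboratory-error pool")
  if (is.na(n) || n < 1L) stop_value("number of resampled dates is undefined")
  if (!is.null(seed)) set.seed(seed)
  window_idx <- match(spd$cal_bp, curve$cal_bp)
  if (anyNA(window_idx))
    stop_alignment("SPD grid is not a sub-grid of the curve")
  members <- matrix(0, n_iter, length(spd$cal_bp))
  for (k in seq_len(n_iter))
    members[k, ] <- .simulate_spd_once(n, spd$cal_bp, spd$density, errors,
                                       curve, window_idx)
  spd_ensemble(spd$cal_bp, members, ci_level, kind = "bootstrap",
               seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Fit an exponential null model to an SPD
#'
#' Least-squares fit of \eqn{y(t) = s\,e^{r\,(t_0 - t)}} (exponential growth
#' in forward time from the window's old edge \eqn{t_0}) to the SPD density.
#' The amplitude is profiled out, leaving a one-dimensional optimisation over
#' the rate.  The annualised growth-rate percentage is
#' \eqn{100\,(e^{r} - 1)}.
#'
#' @param spd an [spd_curve()].
#' @param window optional `c(t_max, t_min)` restriction.
#' @param rate_bounds search interval for the per-year rate.
#' @return An object of class `exp_null` with `rate`, `scale`, `t0`,
#'   `annual_rate_percent`, `fit_window` and `fit_quality` (the correlation
#'   of fit and data).
#' @export
fit_exponential_null <- function(spd, window = NULL,
                                 rate_bounds = c(-5e-3, 5e-3)) {
  if (!is.null(window)) spd <- trim_window(spd, window)
  y <- spd$density
  if (all(y <= 0)) stop_model("SPD density is non-positive everywhere")
  t0 <- max(spd$cal_bp)
  tau <- t0 - spd$cal_bp
  tau_c <- tau - mean(tau)
  rss_of <- function(r) {
    e <- exp(r * tau_c)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  opt <- stats::optimize(rss_of, interval = rate_bounds, tol = 1e-12)
  r <- opt$minimum
  e <- exp(r * tau_c)
  a <- sum(y * e) / sum(e * e)
  fitted <- a * e
  quality <- if (stats::sd(y) > 0 && stats::sd(fitted) > 0)
    stats::cor(y, fitted) else NA_real_
  structure(list(rate = r, scale = a * exp(-r * mean(tau)), t0 = t0,
                 annual_rate_percent = 100 * (exp(r) - 1),
                 fit_window = c(t0, min(spd$cal_bp)),
                 fit_quality = quality),
            class = "exp_null")
}

#' @export
print.exp_null <- function(x, ...) {
  cat("<exp_null> annualized growth rate ",
      format(x$annual_rate_percent, digits = 4), "% per yr (r = ",
      format(x$rate, digits = 4), "/yr), window ", x$fit_window[1], "-",
      x$fit_window[2], " cal BP, fit r = ", format(x$fit_quality, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted null model on a grid
#' @param object an `exp_null`.
#' @param cal_bp calendar grid.
#' @param ... unused.
#' @return Null density values.
#' @export
predict.exp_null <- function(object, cal_bp, ...) {
  object$scale * exp(object$rate * (object$t0 - cal_bp))
}

#' Simulate the exponential null ensemble
#'
#' Draws `n_sim` simulated date sets of `n_dates` calendar ages each from the
#' fitted null density over the window, pushes them through back-calibration,
#' error permutation and recalibration exactly as the bootstrap does, and
#' returns the resulting envelope.  A proportion of simulated dates can be
#' allocated to a marine curve to check robustness to curve choice.
#'
#' @param null an `exp_null` (see [fit_exponential_null()]).
#' @param n_dates dates per simulation (the observed bin count).
#' @param errors empirical laboratory-error pool.
#' @param curve [cal_curve()] for back-/re-calibration.
#' @param n_sim number of simulations.
#' @param seed integer seed or `NULL`.
#' @param window simulation window `c(t_max, t_min)`; defaults to the null
#'   fit window.
#' @param ci_level band level in percent.
#' @param marine optional list `(curve =, proportion =)` assigning each
#'   simulated date to the marine curve with that probability.
#' @return An [spd_ensemble()] with `kind = "null"`.
#' @export
simulate_null <- function(null, n_dates, errors, curve, n_sim = 1000,
                          seed = NULL, window = NULL, ci_level = 95.4,
                          marine = NULL) {
  if (n_dates < 1L) stop_value("n_dates must be positive")
  if (length(errors) == 0L) stop_value("empty laboratory-error pool")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(window)) window <- null$fit_window
  grid <- seq(min(window), max(window))
  window_idx <- match(grid, curve$cal_bp)
  if (anyNA(window_idx))
    stop_alignment("window is not covered by the curve grid")
  prob <- predict(null, grid)
  members <- matrix(0, n_sim, length(grid))
  for (k in seq_len(n_sim))
    members[k, ] <- .simulate_spd_once(n_dates, grid, prob, errors, curve,
                                       window_idx, marine)
  spd_ensemble(grid, members, ci_level, kind = "null",
               seed = if (is.null(seed)) NA_integer_ else seed)
}

# out-of-envelope deviation area of one curve against a band
.departure_statistic <- function(y, lower, upper) {
  sum(pmax(0, y - upper) + pmax(0, lower - y))
}

#' Locate significant departures from a null envelope
#'
#' Finds the maximal runs where the observed curve exceeds the upper band
#' (positive departures) or falls below the lower band (negative), and the
#' global deviation statistic: the total area of the observed curve outside
#' the envelope.  The observed SPD is normalised to unit mass to match the
#' ensemble members' scale.
#'
#' @param observed an [spd_curve()] on the ensemble grid.
#' @param ensemble an [spd_ensemble()].
#' @return An object of class `departure_summary`: data frame `regions`
#'   (`start`, `end` in cal BP with start the older edge, `sign`), and
#'   `global_statistic`.
#' @export
find_departures <- function(observed, ensemble) {
  if (!isTRUE(all.equal(observed$cal_bp, ensemble$cal_bp)))
    stop_alignment("observed SPD and ensemble are not on the same grid")
  y <- observed$density
  if (!observed$normalized) y <- y / sum(y)
  state <- ifelse(y > ensemble$upper, 1L, ifelse(y < ensemble$lower, -1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  regions <- data.frame(
    start = observed$cal_bp[ends[keep]],     # older edge (larger cal BP)
    end = observed$cal_bp[starts[keep]],
    sign = ifelse(r$values[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  regions <- regions[order(-regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 global_statistic = .departure_statistic(y, ensemble$lower,
                                                         ensemble$upper)),
            class = "departure_summary")
}

#' @export
print.departure_summary <- function(x, ...) {
  cat("<departure_summary> ", nrow(x$regions), " regions, statistic ",
      format(x$global_statistic, digits = 4), "\n", sep = "")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Global p-value of the departure statistic
#'
#' Rank-based Monte-Carlo p-value: each simulated member's deviation
#' statistic is computed against the ensemble's own envelope, and
#' \eqn{p = (1 + \#\{sims \ge observed\}) / (1 + n_{sim})}.  The +1 estimator
#' never returns zero and matches permutation-test convention.
#'
#' @param observed_statistic statistic from [find_departures()].
#' @param ensemble the null [spd_ensemble()].
#' @return The p-value, with the member statistics attached as attribute
#'   `sim_statistics`.
#' @export
global_pvalue <- function(observed_statistic, ensemble) {
  sims <- apply(ensemble$members, 1L, .departure_statistic,
                lower = ensemble$lower, upper = ensemble$upper)
  p <- (1 + sum(sims >= observed_statistic)) / (1 + length(sims))
  attr(p, "sim_statistics") <- sims
  p
}

#' Regional subsampling null ensemble
#'
#' Builds the null model for a regional record by repeatedly subsampling,
#' without replacement, the panregional pool of calibrated bins with the
#' same number of bins the region contributes, and summing each subsample
#' into a unit-mass SPD.  Departures of the regional SPD from this envelope
#' flag region-specific dynamics beyond the panregional trend.
#'
#' @param regional_bins list of the region's bins (each a list of
#'   `cal_density`), used only for its count.
#' @param panregional_bins list of all bins in the panregional record.
#' @param window calendar window `c(t_max, t_min)`.
#' @param n_sim number of subsamples.
#' @param seed integer seed or `NULL`.
#' @param ci_level band level in percent.
#' @return An [spd_ensemble()] with `kind = "subsample"`.
#' @export
regional_null <- function(regional_bins, panregional_bins, window,
                          n_sim = 1000, seed = NULL, ci_level = 95.4) {
  n_reg <- length(regional_bins)
  if (n_reg == 0L) stop_value("regional record is empty")
  if (n_reg > length(panregional_bins))
    stop_value("regional bin count exceeds the panregional pool")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(min(window), max(window))
  # precompute each bin's mean member density on the grid
  B <- matrix(0, length(panregional_bins), length(grid))
  for (j in seq_along(panregional_bins)) {
    bin <- panregional_bins[[j]]
    for (d in bin) {
      i <- match(d$cal_bp, grid)
      ok <- !is.na(i)
      B[j, i[ok]] <- B[j, i[ok]] + d$mass[ok]
    }
    B[j, ] <- B[j, ] / length(bin)
  }
  members <- matrix(0, n_sim, length(grid))
  for (k in seq_len(n_sim)) {
    pick <- sample.int(nrow(B), n_reg, replace = FALSE)
    v <- colSums(B[pick, , drop = FALSE])
    s <- sum(v)
    members[k, ] <- if (s > 0) v / s else v
  }
  spd_ensemble(grid, members, ci_level, kind = "subsample",
               seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Write an ensemble summary to CSV
#' @param ensemble an [spd_ensemble()].
#' @param path output path; columns `cal_bp`, `lower`, `median`, `upper`.
#' @export
write_ensemble <- function(ensemble, path) {
  utils::write.csv(data.frame(cal_bp = ensemble$cal_bp,
                              lower = ensemble$lower,
                              median = ensemble$median_curve,
                              upper = ensemble$upper),
                   path, row.names = FALSE)
  invisible(path)
}
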