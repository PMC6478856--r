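#' Palaeoenvironmental proxy series
#'
#' A `proxy_series` is a time series of an environmental indicator (ice-core
#' delta-18O, sea-surface temperature, arboreal pollen percentage, ...) on a
#' strictly monotonic calendar-age axis, consumed as given: no age-model or
#' chronology work is done here.
#'
#' @param cal_bp sample ages, cal BP, strictly monotonic.
#' @param value proxy values (no missing values).
#' @param label series label.
#' @return An object of class `proxy_series`.
#' @export
proxy_series <- function(cal_bp, value, label = "proxy") {
  if (length(cal_bp) != length(value))
    stop_value("cal_bp and value lengths differ")
  if (anyNA(value) || anyNA(cal_bp))
    stop_value("proxy series must not contain missing values")
  d <- diff(cal_bp)
  if (!(all(d > 0) || all(d < 0)))
    stop_value("proxy ages must be strictly monotonic")
  if (all(d < 0)) { cal_bp <- rev(cal_bp); value <- rev(value) }
  structure(list(cal_bp = as.numeric(cal_bp), value = as.numeric(value),
                 label = label),
            class = "proxy_series")
}

#' Read a proxy series from CSV
#' @param path CSV with columns `cal_bp`, `value`.
#' @param label series label (defaults to the file name).
#' @return A [proxy_series()].
#' @export
read_proxy <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  if (!all(c("cal_bp", "value") %in% names(df)))
    stop_schema("proxy CSV must have columns cal_bp and value")
  proxy_series(df$cal_bp, df$value, label)
}

#' Align a proxy series onto a calendar grid
#'
#' Linear interpolation onto the SPD grid; when the proxy is sampled more
#' densely than the grid, block means over grid cells are used instead so no
#' high-frequency information aliases in.  The result is trimmed to the
#' intersection of the two ranges.
#'
#' @param proxy a [proxy_series()].
#' @param grid target calendar grid (ascending cal BP).
#' @return A [proxy_series()] on (the covered part of) `grid`.
#' @export
align_series <- function(proxy, grid) {
  step <- stats::median(diff(grid))
  lo <- max(min(grid), min(proxy$cal_bp))
  hi <- min(max(grid), max(proxy$cal_bp))
  if (lo > hi) stop_range("proxy and grid ranges do not intersect")
  g <- grid[grid >= lo & grid <= hi]
  if (length(g) == 0L) stop_range("proxy and grid ranges do not intersect")
  proxy_step <- stats::median(diff(proxy$cal_bp))
  if (proxy_step < step) {
    cell <- findInterval(proxy$cal_bp, g - step / 2)
    ok <- cell >= 1L & cell <= length(g)
    means <- tapply(proxy$value[ok], cell[ok], mean)
    v <- rep(NA_real_, length(g))
    v[as.integer(names(means))] <- means
    if (anyNA(v))
      v <- stats::approx(g[!is.na(v)], v[!is.na(v)], xout = g, rule = 2)$y
  } else {
    v <- stats::approx(proxy$cal_bp, proxy$value, xout = g)$y
  }
  proxy_series(g, v, proxy$label)
}

#' Rank correlation between an SPD ensemble and a proxy
#'
#' Spearman's rank correlation of each bootstrap member against the aligned
#' proxy, so the spread of coefficients expresses the uncertainty that
#' radiocarbon measurement and calibration contribute.  Ties are mid-ranked.
#' The p-value is computed from the member-median coefficient with the usual
#' t approximation.
#'
#' @param ensemble an [spd_ensemble()].
#' @param proxy a [proxy_series()].
#' @param window optional `c(t_max, t_min)` restriction in cal BP.
#' @return A list with `mean_rho`, `sd_rho`, `median_rho`, `p`, `n_points`,
#'   `n_members`.
#' @export
spearman_ensemble <- function(ensemble, proxy, window = NULL) {
  grid <- ensemble$cal_bp
  keep <- rep(TRUE, length(grid))
  if (!is.null(window))
    keep <- grid >= min(window) & grid <= max(window)
  al <- align_series(proxy, grid[keep])
  idx <- which(keep)[match(al$cal_bp, grid[keep])]
  if (length(idx) < 3L)
    stop_value("fewer than 3 aligned points in the correlation window")
  if (stats::sd(al$value) == 0)
    stop_value("proxy is constant in the window: correlation undefined")
  rhos <- apply(ensemble$members[, idx, drop = FALSE], 1L, function(m) {
    if (stats::sd(m) == 0) return(NA_real_)
    stats::cor(m, al$value, method = "spearman")
  })
  if (all(is.na(rhos)))
    stop_value("all ensemble members are constant in the window: correlation undefined")
  rho_med <- stats::median(rhos, na.rm = TRUE)
  n <- length(idx)
  tval <- rho_med * sqrt((n - 2) / max(1e-12, 1 - rho_med^2))
  list(mean_rho = mean(rhos, na.rm = TRUE),
       sd_rho = stats::sd(rhos, na.rm = TRUE),
       median_rho = rho_med,
       p = 2 * stats::pt(-abs(tval), df = n - 2),
       n_points = n, n_members = sum(!is.na(rhos)))
}

#' Detrended variance of a proxy series
#'
#' Short-term environmental instability indicator: an ordinary least-squares
#' line is removed from the series and the population variance of the
#' residuals is returned, in squared proxy units.
#'
#' @param proxy a [proxy_series()].
#' @param window optional `c(t_max, t_min)` restriction in cal BP.
#' @return Residual variance (population definition).
#' @export
detrended_variance <- function(proxy, window = NULL) {
  t <- proxy$cal_bp; v <- proxy$value
  if (!is.null(window)) {
    keep <- t >= min(window) & t <= max(window)
    t <- t[keep]; v <- v[keep]
  }
  if (length(v) < 3L) stop_value("need at least 3 points")
  res <- stats::lm.fit(cbind(1, t), v)$residuals
  mean(res^2)
}
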