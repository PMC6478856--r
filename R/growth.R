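#' Piecewise demographic growth models
#'
#' Six candidate models of long-term population dynamics are fitted to the
#' population proxy and ranked by information criteria:
#'
#' * **A** - single-phase exponential growth;
#' * **B** - single-phase logistic (density-dependent) growth;
#' * **C** - exponential / exponential, one breakpoint;
#' * **D** - exponential / logistic, one breakpoint;
#' * **E** - exponential / decay-to-limit / exponential, two breakpoints;
#' * **F** - exponential / decay-to-limit / logistic, two breakpoints.
#'
#' All model arithmetic runs in forward time \eqn{\tau} (years elapsed since
#' the old edge of the fitted window), with each phase parameterised in its
#' own local time from the phase start.  Phase forms are
#' exponential \eqn{\alpha e^{r\tau}}, logistic
#' \eqn{A/(1+e^{(x_0-\tau)/s}) + c}, and decay-to-limit
#' \eqn{a e^{-b\tau} + c}.  Breakpoints are scanned in 1-year increments
#' within `half_width` of their climatic anchor points (defaults: the onset
#' of the Younger Dryas near 12.9 kya and of the Early Mesolithic near
#' 10.2 kya), and every phase must last at least `min_phase` years.
#'
#' @param model_id one of `"A"`..`"F"`.
#' @param breakpoints scan centres in cal BP, oldest first; the model uses as
#'   many as it needs.
#' @param half_width scan half-width in years around each centre.
#' @param min_phase minimum phase duration in years.
#' @return An object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(model_id, breakpoints = c(12900, 10200),
                              half_width = 150, min_phase = 2000) {
  phases <- switch(toupper(model_id),
    A = "exponential",
    B = "logistic",
    C = c("exponential", "exponential"),
    D = c("exponential", "logistic"),
    E = c("exponential", "decay_to_limit", "exponential"),
    F = c("exponential", "decay_to_limit", "logistic"),
    stop_spec(sprintf("unknown model id '%s'", model_id)))
  n_bp <- length(phases) - 1L
  if (length(breakpoints) < n_bp)
    stop_spec(sprintf("model %s needs %d breakpoint centre(s)", model_id, n_bp))
  bp <- if (n_bp > 0L) sort(breakpoints, decreasing = TRUE)[seq_len(n_bp)]
        else numeric()
  structure(list(model_id = toupper(model_id), phases = phases,
                 breakpoints = bp, half_width = half_width,
                 min_phase = min_phase),
            class = "growth_model_spec")
}

# parameter counts per phase form
.phase_k <- c(exponential = 2L, logistic = 4L, decay_to_limit = 3L)

# evaluate one phase form in local phase time (tl = years since phase start)
.eval_phase <- function(form, par, tl) {
  switch(form,
         exponential = par[["alpha"]] * exp(par[["rate"]] * tl),
         logistic = par[["A"]] * stats::plogis((tl - par[["x0"]]) / par[["s"]]) +
           par[["c"]],
         decay_to_limit = par[["a"]] * exp(-par[["b"]] * tl) + par[["c"]],
         stop_spec(sprintf("unknown phase form '%s'", form)))
}

#' Evaluate a piecewise growth model
#'
#' @param phases character vector of phase forms.
#' @param params list of named parameter vectors, one per phase
#'   (exponential: `alpha`, `rate`; logistic: `A`, `x0`, `s`, `c`;
#'   decay-to-limit: `a`, `b`, `c`).  Parameters are in local phase time.
#' @param tau forward-time grid (years since window start), ascending.
#' @param tau_breaks forward-time positions of the breakpoints.
#' @return Model curve values at `tau`.
#' @export
model_curve <- function(phases, params, tau, tau_breaks = numeric()) {
  if (length(params) != length(phases))
    stop_spec("one parameter vector per phase is required")
  if (length(tau_breaks) != length(phases) - 1L)
    stop_spec("phase count must equal breakpoint count + 1")
  for (p in seq_along(phases)) {
    need <- switch(phases[p], exponential = c("alpha", "rate"),
                   logistic = c("A", "x0", "s", "c"),
                   decay_to_limit = c("a", "b", "c"))
    if (!all(need %in% names(params[[p]])))
      stop_spec(sprintf("phase %d (%s) is missing parameters", p, phases[p]))
  }
  edges <- c(-Inf, tau_breaks, Inf)
  y <- numeric(length(tau))
  starts <- c(0, tau_breaks)
  for (p in seq_along(phases)) {
    i <- tau >= edges[p] & tau < edges[p + 1L]
    if (p == length(phases)) i <- tau >= edges[p]
    y[i] <- .eval_phase(phases[p], params[[p]], tau[i] - starts[p])
  }
  y
}

# --- phase fitters (variable projection: linear parameters profiled out) ----

.lin2 <- function(z, y) {
  # least squares for y ~ a*z + c; returns c(a, c, rss)
  n <- length(y)
  Sz <- sum(z); Szz <- sum(z * z); Sy <- sum(y); Szy <- sum(z * y)
  det <- n * Szz - Sz^2
  if (!is.finite(det) || det <= 1e-12 * (n * Szz + 1e-300))
    return(c(0, Sy / n, sum((y - Sy / n)^2)))
  a <- (n * Szy - Sz * Sy) / det
  cc <- (Szz * Sy - Sz * Szy) / det
  c(a, cc, sum((y - a * z - cc)^2))
}

.fit_phase_exponential <- function(tl, y, rate_bounds = c(-0.02, 0.02)) {
  tc <- tl - mean(tl)
  rss_of <- function(r) {
    e <- exp(r * tc)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  opt <- stats::optimize(rss_of, interval = rate_bounds, tol = 1e-10)
  r <- opt$minimum
  e <- exp(r * tc)
  a <- sum(y * e) / sum(e * e)
  list(par = c(alpha = a * exp(-r * mean(tl)), rate = r),
       rss = sum((y - a * e)^2), k = 2L)
}

.fit_phase_decay <- function(tl, y, b_bounds = c(1e-6, 0.05)) {
  rss_of <- function(b) .lin2(exp(-b * tl), y)[3L]
  opt <- stats::optimize(rss_of, interval = b_bounds, tol = 1e-9)
  b <- opt$minimum
  sol <- .lin2(exp(-b * tl), y)
  list(par = c(a = sol[1L], b = b, c = sol[2L]), rss = sol[3L], k = 3L)
}

.fit_phase_logistic <- function(tl, y, s_min = 25) {
  # The midpoint is constrained to the phase window and the transition width
  # to at least ~one human generation: a logistic step sharper than that is a
  # calibration artefact, not demography.
  span <- max(tl) - min(tl)
  s_max <- max(span, s_min * 2)
  to_x0 <- function(q) min(tl) + span * stats::plogis(q)
  to_s <- function(q) s_min + (s_max - s_min) * stats::plogis(q)
  from_unit <- function(u) stats::qlogis(pmin(0.999, pmax(0.001, u)))
  obj <- function(p)
    .lin2(stats::plogis((tl - to_x0(p[1L])) / to_s(p[2L])), y)[3L]
  # initial midpoint guesses: steepest gradient of a lightly smoothed curve,
  # plus fixed fractions of the span
  k <- max(3L, min(11L, length(y) %/% 10L))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  dy <- abs(diff(as.numeric(ys)))
  x0_grad <- tl[which.max(replace(dy, is.na(dy), -Inf))]
  starts <- expand.grid(
    x0 = from_unit((unique(c(x0_grad, min(tl) + span * c(0.25, 0.5))) -
                      min(tl)) / span),
    s = from_unit((span / c(20, 60) - s_min) / (s_max - s_min)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$x0[i], starts$s[i]), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  x0 <- to_x0(best$par[1L]); s <- to_s(best$par[2L])
  sol <- .lin2(stats::plogis((tl - x0) / s), y)
  list(par = c(A = sol[1L], x0 = x0, s = s, c = sol[2L]),
       rss = sol[3L], k = 4L)
}

.fit_phase <- function(form, tl, y) {
  switch(form,
         exponential = .fit_phase_exponential(tl, y),
         logistic = .fit_phase_logistic(tl, y),
         decay_to_limit = .fit_phase_decay(tl, y))
}

# ---------------------------------------------------------------------------

.proxy_frame <- function(proxy) {
  if (inherits(proxy, "spd_ensemble")) proxy <- ensemble_median(proxy)
  if (inherits(proxy, "spd"))
    proxy <- data.frame(cal_bp = proxy$cal_bp, density = proxy$density)
  if (!is.data.frame(proxy) || !all(c("cal_bp", "density") %in% names(proxy)))
    stop_value("proxy must be an spd, an spd_ensemble, or a data frame with cal_bp and density")
  proxy[order(-proxy$cal_bp), , drop = FALSE]
}

#' Fit one piecewise growth model to the population proxy
#'
#' For each candidate breakpoint combination on the scan grid, every phase is
#' least-squares fitted independently on its sub-window, and the combination
#' minimising the total RSS is kept.  The fit is deterministic and, because
#' each phase fit is scale-equivariant, derived growth rates are invariant to
#' rescaling of the proxy.
#'
#' @param proxy an [spd_curve()], [spd_ensemble()] (its median is used; the
#'   bootstrap median is the recommended fit target) or a data frame with
#'   columns `cal_bp`, `density`.
#' @param spec a [growth_model_spec()] or a model id `"A"`..`"F"`.
#' @param scan `"coarse"` (coarse-to-fine refinement ending on the 1-year
#'   grid; default) or `"exhaustive"` (full 1-year scan).
#' @param thin fit on every `thin`-th grid point (1 = all points).
#' @param ... passed to [growth_model_spec()] when `spec` is a model id.
#' @return An object of class `growth_model_fit`.
#' @export
fit_model <- function(proxy, spec, scan = c("coarse", "exhaustive"),
                      thin = 1L, ...) {
  scan <- match.arg(scan)
  if (is.character(spec)) spec <- growth_model_spec(spec, ...)
  pf <- .proxy_frame(proxy)
  t0 <- max(pf$cal_bp)
  tau_all <- t0 - pf$cal_bp              # ascending
  y_all <- pf$density
  idx <- seq(1L, length(tau_all), by = as.integer(thin))
  tau <- tau_all[idx]; y <- y_all[idx]
  tau_max <- max(tau_all)
  n_bp <- length(spec$phases) - 1L

  memo <- new.env(parent = emptyenv())
  fit_phase_memo <- function(p, lo, hi) {
    key <- paste(p, lo, hi)
    if (!is.null(memo[[key]])) return(memo[[key]])
    i <- tau >= lo & (if (hi >= tau_max) tau <= hi else tau < hi)
    f <- .fit_phase(spec$phases[p], tau[i] - lo, y[i])
    memo[[key]] <- f
    f
  }
  total_rss <- function(tau_bp) {
    edges <- c(0, tau_bp, tau_max)
    if (any(diff(edges) < spec$min_phase)) return(Inf)
    tot <- 0
    for (p in seq_along(spec$phases))
      tot <- tot + fit_phase_memo(p, edges[p], edges[p + 1L])$rss
    tot
  }

  if (n_bp == 0L) {
    best_bp <- numeric()
    best_rss <- total_rss(numeric())
  } else {
    centres_tau <- t0 - spec$breakpoints   # ascending in tau
    evaluate <- function(cand) {
      # cand: list of candidate vectors per breakpoint (tau scale)
      combos <- as.matrix(expand.grid(cand))
      vals <- apply(combos, 1L, function(v)
        if (is.unsorted(v, strictly = TRUE)) Inf else total_rss(v))
      list(bp = combos[which.min(vals), ], rss = min(vals))
    }
    clip <- function(v, ctr) v[v >= ctr - spec$half_width &
                               v <= ctr + spec$half_width]
    if (scan == "exhaustive") {
      cand <- lapply(centres_tau, function(ctr)
        seq(ctr - spec$half_width, ctr + spec$half_width, by = 1))
      best <- evaluate(cand)
    } else {
      steps <- c(30, 5, 1)
      at <- centres_tau
      radius <- rep(spec$half_width, n_bp)
      best <- NULL
      for (s in steps) {
        cand <- lapply(seq_len(n_bp), function(j)
          clip(seq(at[j] - radius[j], at[j] + radius[j], by = s),
               centres_tau[j]))
        best <- evaluate(cand)
        at <- as.numeric(best$bp)
        radius <- rep(s, n_bp)
      }
    }
    if (!is.finite(best$rss))
      stop_spec("no feasible breakpoint combination satisfies the minimum phase duration")
    best_bp <- as.numeric(best$bp)
    best_rss <- best$rss
  }

  edges <- c(0, best_bp, tau_max)
  params <- vector("list", length(spec$phases))
  k <- n_bp
  for (p in seq_along(spec$phases)) {
    f <- fit_phase_memo(p, edges[p], edges[p + 1L])
    params[[p]] <- f$par
    k <- k + f$k
  }
  n <- length(y)
  fitted_vals <- model_curve(spec$phases, params, tau, best_bp)
  structure(list(model_id = spec$model_id, spec = spec, params = params,
                 tau_breaks = best_bp, breakpoints_cal_bp = t0 - best_bp,
                 t0 = t0, tau_max = tau_max,
                 cal_bp = pf$cal_bp[idx], y = y, fitted = fitted_vals,
                 rss = best_rss, k = k, n = n,
                 aic = .ic(best_rss, n, k, 2),
                 sbc = .ic(best_rss, n, k, log(n)),
                 scan = scan, thin = as.integer(thin)),
            class = "growth_model_fit")
}

# Gaussian-RSS information criterion with a perfect-fit sentinel: an exactly
# zero RSS ranks first under any penalty.
.ic <- function(rss, n, k, penalty) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + penalty * k
}

#' Fit and rank all candidate growth models
#'
#' The main entry point of the model-selection stage: fits each requested
#' model with [fit_model()] and ranks them by AIC and SBC.
#'
#' @inheritParams fit_model
#' @param models model ids to fit.
#' @param breakpoints,half_width,min_phase passed to [growth_model_spec()].
#' @return An object of class `growth_model_set`: named list `fits`, the
#'   `ranking` table (see [rank_models()]) and `best` (model id with lowest
#'   AIC).
#' @examples
#' \donttest{
#' cc <- make_synthetic_curve("identity", c(500, 11000), sigma = 10)
#' tau <- 0:8000
#' y <- 0.0001 * exp(2e-4 * tau)
#' proxy <- data.frame(cal_bp = 10000 - tau, density = y)
#' fits <- fit_growth_models(proxy, models = c("A", "B"), thin = 10)
#' fits$best
#' }
#' @export
fit_growth_models <- function(proxy, models = c("A", "B", "C", "D", "E", "F"),
                              breakpoints = c(12900, 10200), half_width = 150,
                              min_phase = 2000,
                              scan = c("coarse", "exhaustive"), thin = 1L) {
  scan <- match.arg(scan)
  fits <- lapply(models, function(m)
    fit_model(proxy, growth_model_spec(m, breakpoints, half_width, min_phase),
              scan = scan, thin = thin))
  names(fits) <- toupper(models)
  ranking <- rank_models(fits)
  structure(list(fits = fits, ranking = ranking,
                 best = ranking$model_id[1L]),
            class = "growth_model_set")
}

#' Rank fitted growth models by information criteria
#'
#' Gaussian-RSS criteria: `aic = n log(rss/n) + 2k`,
#' `sbc = n log(rss/n) + k log(n)`, with `k` counting every free parameter
#' including each scanned breakpoint.  Ties are broken by model id for a
#' stable order.
#'
#' @param fits list of `growth_model_fit` objects on the same proxy.
#' @return A data frame sorted by AIC with columns `model_id`, `rss`, `k`,
#'   `aic`, `sbc`, `breakpoints`, and attribute `criteria_agree` flagging
#'   whether AIC and SBC give the same order.
#' @export
rank_models <- function(fits) {
  ns <- vapply(fits, function(f) as.numeric(f$n), 0)
  if (length(unique(ns)) > 1L)
    stop_value("fits were made on different numbers of points; not comparable")
  df <- data.frame(
    model_id = vapply(fits, `[[`, "", "model_id"),
    rss = vapply(fits, `[[`, 0, "rss"),
    k = vapply(fits, function(f) as.numeric(f$k), 0),
    aic = vapply(fits, `[[`, 0, "aic"),
    sbc = vapply(fits, `[[`, 0, "sbc"),
    breakpoints = vapply(fits, function(f)
      paste(round(f$breakpoints_cal_bp), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  o_aic <- order(df$aic, df$model_id)
  o_sbc <- order(df$sbc, df$model_id)
  df <- df[o_aic, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "criteria_agree") <- identical(o_aic, o_sbc)
  df
}

# ------------------------------ S3 methods ---------------------------------

#' @export
print.growth_model_fit <- function(x, ...) {
  cat("<growth_model_fit> model ", x$model_id, ": ",
      paste(x$spec$phases, collapse = " / "), "\n", sep = "")
  if (length(x$breakpoints_cal_bp))
    cat("  breakpoints: ", paste(round(x$breakpoints_cal_bp), collapse = ", "),
        " cal BP\n", sep = "")
  cat("  rss = ", format(x$rss, digits = 5), ", k = ", x$k, ", n = ", x$n,
      ", AIC = ", format(x$aic, digits = 6), ", SBC = ",
      format(x$sbc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.growth_model_fit <- function(object, ...) {
  out <- numeric()
  for (p in seq_along(object$params)) {
    v <- object$params[[p]]
    names(v) <- paste0("phase", p, ".", object$spec$phases[p], ".", names(v))
    out <- c(out, v)
  }
  out
}

#' @export
predict.growth_model_fit <- function(object, cal_bp = NULL, ...) {
  if (is.null(cal_bp)) cal_bp <- object$cal_bp
  tau <- object$t0 - cal_bp
  model_curve(object$spec$phases, object$params, tau, object$tau_breaks)
}

#' @export
fitted.growth_model_fit <- function(object, ...) object$fitted

#' @export
residuals.growth_model_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.growth_model_fit <- function(x, ..., xlab = "cal BP",
                                  ylab = "population proxy") {
  graphics::plot(x$cal_bp, x$y, type = "l", col = "grey40",
                 xlim = rev(range(x$cal_bp)), xlab = xlab, ylab = ylab, ...)
  graphics::lines(x$cal_bp, x$fitted, col = "red", lwd = 2)
  if (length(x$breakpoints_cal_bp))
    graphics::abline(v = x$breakpoints_cal_bp, lty = 2, col = "grey60")
  invisible(x)
}

#' @export
summary.growth_model_fit <- function(object, ...) {
  gr <- growth_rate(object)
  structure(list(fit = object, phase_rates = attr(gr, "phase_rates")),
            class = "summary.growth_model_fit")
}

#' @export
print.summary.growth_model_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-phase annual growth rates (%):\n")
  print(x$phase_rates, row.names = FALSE)
  invisible(x)
}

#' @export
print.growth_model_set <- function(x, ...) {
  cat("<growth_model_set> best model by AIC: ", x$best, "\n", sep = "")
  print(x$ranking)
  if (isTRUE(attr(x$ranking, "criteria_agree")))
    cat("AIC and SBC rankings agree\n")
  invisible(x)
}

#' @export
plot.growth_model_set <- function(x, model = x$best, ...) {
  plot(x$fits[[model]], ...)
}

#' @export
summary.growth_model_set <- function(object, ...) {
  summary(object$fits[[object$best]])
}

#' Draw calendar ages from a fitted growth model
#'
#' Samples calendar ages in proportion to the fitted model curve, the
#' forward step used when turning a fitted demography back into simulated
#' date sets.
#'
#' @param object a `growth_model_fit`.
#' @param nsim number of replicate draws.
#' @param seed optional integer seed.
#' @param n_dates ages per replicate.
#' @param ... unused.
#' @return A list of `nsim` numeric vectors of calendar ages BP.
#' @export
simulate.growth_model_fit <- function(object, nsim = 1, seed = NULL,
                                      n_dates = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  y <- pmax(0, object$fitted)
  lapply(seq_len(nsim), function(i)
    sample(object$cal_bp, n_dates, replace = TRUE, prob = y))
}

# ----------------------------- growth rates --------------------------------

#' Annual growth-rate series of a fitted model
#'
#' The discrete annual rate \eqn{100\,(y(\tau+1)/y(\tau) - 1)}, which equals
#' \eqn{100\,(e^{r} - 1)} for a pure exponential phase.  Rates are computed
#' within phases (the jump across a breakpoint is not a growth rate and is
#' reported as `NA` at the boundary).
#'
#' @param fit a `growth_model_fit`.
#' @param cal_bp grid to evaluate on; defaults to the fit grid.
#' @return A data frame (class `growth_rate_series`) with `cal_bp` and
#'   `rate_percent`, and attribute `phase_rates`: per-phase mean, min and max
#'   annual rate in percent.
#' @export
growth_rate <- function(fit, cal_bp = NULL) {
  if (is.null(cal_bp)) cal_bp <- fit$cal_bp
  tau <- fit$t0 - cal_bp
  edges <- c(0, fit$tau_breaks, fit$tau_max)
  starts <- c(0, fit$tau_breaks)
  rate <- rep(NA_real_, length(tau))
  phase_rows <- list()
  for (p in seq_along(fit$spec$phases)) {
    i <- which(tau >= edges[p] &
                 (if (p == length(fit$spec$phases)) tau <= edges[p + 1L]
                  else tau < edges[p + 1L]))
    if (length(i) == 0L) next
    tl <- tau[i] - starts[p]
    y0 <- .eval_phase(fit$spec$phases[p], fit$params[[p]], tl)
    if (any(y0 <= 0))
      stop_model("fitted curve is non-positive; growth rate undefined")
    y1 <- .eval_phase(fit$spec$phases[p], fit$params[[p]], tl + 1)
    r <- 100 * (y1 / y0 - 1)
    # the last point of a phase looks into the next phase: not a within-phase rate
    in_phase <- (tl + 1) <= (edges[p + 1L] - starts[p])
    rate[i] <- ifelse(in_phase, r, NA_real_)
    rr <- r[in_phase]
    phase_rows[[p]] <- data.frame(
      phase = p, form = fit$spec$phases[p],
      start_cal_bp = fit$t0 - edges[p], end_cal_bp = fit$t0 - edges[p + 1L],
      mean_rate = mean(rr), min_rate = min(rr), max_rate = max(rr))
  }
  out <- data.frame(cal_bp = cal_bp, rate_percent = rate)
  class(out) <- c("growth_rate_series", "data.frame")
  attr(out, "phase_rates") <- do.call(rbind, phase_rows)
  out
}

#' @export
plot.growth_rate_series <- function(x, ..., xlab = "cal BP",
                                    ylab = "annual growth rate (%)") {
  graphics::plot(x$cal_bp, x$rate_percent, type = "l",
                 xlim = rev(range(x$cal_bp)), xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Uncertainty of per-phase growth rates
#'
#' Re-derives the per-phase rate summaries across the breakpoint scan range
#' (each breakpoint displaced on a grid within the scan half-width, phases
#' refitted) and, optionally, across bootstrap ensemble members (phases
#' refitted on each member), and returns the envelope of the resulting
#' per-phase mean/min/max rates.
#'
#' @param fit a `growth_model_fit`.
#' @param proxy the proxy the fit was made on.
#' @param ensemble optional [spd_ensemble()] of proxy curves.
#' @param bp_step step (years) of the breakpoint displacement grid.
#' @param max_members at most this many ensemble members are refitted.
#' @return Data frame with per-phase `mean_lo`, `mean_hi`, `min_lo`,
#'   `min_hi`, `max_lo`, `max_hi` (annual rate, percent).
#' @export
growth_rate_ci <- function(fit, proxy, ensemble = NULL, bp_step = 50,
                           max_members = 25) {
  offs <- seq(-fit$spec$half_width, fit$spec$half_width, by = bp_step)
  n_bp <- length(fit$tau_breaks)
  bp_sets <- if (n_bp == 0L) list(numeric()) else {
    grids <- lapply(seq_len(n_bp), function(j) fit$tau_breaks[j] + offs)
    g <- as.matrix(expand.grid(grids))
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  proxies <- list(data.frame(cal_bp = fit$cal_bp, density = fit$y))
  if (!is.null(ensemble)) {
    pick <- round(seq(1L, nrow(ensemble$members),
                      length.out = min(max_members, nrow(ensemble$members))))
    for (m in pick)
      proxies <- c(proxies, list(data.frame(cal_bp = ensemble$cal_bp,
                                            density = ensemble$members[m, ])))
  }
  rows <- list()
  for (pr in proxies) {
    pf <- .proxy_frame(pr)
    tau <- fit$t0 - pf$cal_bp; y <- pf$density
    for (bp in bp_sets) {
      edges <- c(0, bp, fit$tau_max)
      if (any(diff(edges) < fit$spec$min_phase)) next
      params <- vector("list", length(fit$spec$phases))
      ok <- TRUE
      for (p in seq_along(fit$spec$phases)) {
        i <- tau >= edges[p] & (if (p == length(fit$spec$phases))
          tau <= edges[p + 1L] else tau < edges[p + 1L])
        if (sum(i) < 5L) { ok <- FALSE; break }
        params[[p]] <- .fit_phase(fit$spec$phases[p], tau[i] - edges[p], y[i])$par
      }
      if (!ok) next
      refit <- fit
      refit$params <- params; refit$tau_breaks <- bp
      refit$breakpoints_cal_bp <- fit$t0 - bp
      pr_rates <- tryCatch(attr(growth_rate(refit), "phase_rates"),
                           paleodem_model_error = function(e) NULL)
      if (!is.null(pr_rates)) rows <- c(rows, list(pr_rates))
    }
  }
  all_rates <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(all_rates, all_rates$phase), function(d)
    data.frame(phase = d$phase[1L], form = d$form[1L],
               mean_lo = min(d$mean_rate), mean_hi = max(d$mean_rate),
               min_lo = min(d$min_rate), min_hi = max(d$min_rate),
               max_lo = min(d$max_rate), max_hi = max(d$max_rate))))
  rownames(out) <- NULL
  out
}

#' Doubling time of a growth rate
#'
#' Years for a population growing at `rate_percent` per year to double:
#' \eqn{\ln 2 / \ln(1 + r/100)}.
#'
#' @param rate_percent annual growth rate in percent (> 0).
#' @return Doubling time in years.
#' @examples
#' doubling_time(0.0411)  # ~1687 yr
#' @export
doubling_time <- function(rate_percent) {
  if (any(rate_percent <= 0)) stop_value("doubling time is undefined for non-positive rates")
  log(2) / log1p(rate_percent / 100)
}

#' Fold change over a time span
#'
#' Total multiplicative population change for a constant annual growth rate:
#' \eqn{(1 + r/100)^{span}}.
#'
#' @param rate_percent annual growth rate in percent.
#' @param span_years elapsed years.
#' @return Fold change.
#' @examples
#' fold_change(0.01958, 10000)  # ~7
#' @export
fold_change <- function(rate_percent, span_years) {
  (1 + rate_percent / 100)^span_years
}
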