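#' Synthetic calibration curves
#'
#' Generates calibration curves with known behaviour so every pipeline stage
#' can be tested without external curve files: `identity`
#' (\eqn{\mu_c(t) = t}), `linear_offset` (\eqn{\mu_c(t) = t + \Delta}) and
#' `wiggly` (\eqn{\mu_c(t) = t + A \sin(2\pi t / P)}, the default test curve:
#' it exercises multimodal calibration).  The wiggle amplitude must keep
#' \eqn{\mu_c} strictly monotonic (\eqn{2\pi A / P < 1}), which is checked.
#'
#' @param kind `"identity"`, `"linear_offset"` or `"wiggly"`.
#' @param range calendar range `c(min, max)` cal BP.
#' @param offset offset in 14C years (linear_offset kind).
#' @param wiggle_amplitude,wiggle_period sine amplitude (14C yr) and period
#'   (yr) of the wiggly kind.
#' @param sigma constant curve one-sigma, 14C yr (0 allowed for noiseless
#'   round-trip testing).
#' @param name curve label.
#' @return A [cal_curve()].
#' @export
make_synthetic_curve <- function(kind = c("wiggly", "identity", "linear_offset"),
                                 range = c(7000, 18500), offset = 400,
                                 wiggle_amplitude = 20, wiggle_period = 500,
                                 sigma = 10, name = NULL) {
  kind <- match.arg(kind)
  grid <- seq(min(range), max(range))
  mu <- switch(kind,
               identity = grid,
               linear_offset = grid + offset,
               wiggly = grid + wiggle_amplitude *
                 sin(2 * pi * grid / wiggle_period))
  if (any(diff(mu) <= 0))
    stop_paleodem("parameter_error",
                  "wiggle amplitude/period make the curve non-monotonic")
  cal_curve(grid, mu, rep(sigma, length(grid)),
            name = if (is.null(name)) paste0("synthetic_", kind) else name)
}

#' Synthetic study scenarios
#'
#' A scenario bundles a known demographic curve (ground truth) with the
#' nuisance structure of a real radiocarbon database: sites with regions and
#' site types, laboratory errors, calibration-curve distortion and optional
#' taphonomic loss of open-air deposits.  Lab errors are drawn from a
#' log-normal truncated below 200 yr, so generated datasets always pass the
#' error filter unless a violation is injected deliberately.
#'
#' @param true_model list with `phases`, `params`, `tau_breaks`, `t0` (see
#'   [model_curve()]); the demographic curve dates are drawn from.
#' @param window calendar window `c(t_max, t_min)` cal BP.
#' @param n_dates number of determinations.
#' @param site_count number of sites.
#' @param episodes_per_site mean number of distinct occupation episodes per
#'   site; dates are assigned to sites in temporally contiguous episode
#'   blocks so per-site binning is meaningful.
#' @param region_mix named proportions over the five regions (sum to 1).
#' @param site_type_mix named proportions over site types (sum to 1).
#' @param error_dist list `meanlog`, `sdlog`, `min`, `cap` for lab errors.
#' @param curve list of [make_synthetic_curve()] arguments (plus
#'   `marine_offset`, the reservoir-age offset of the derived marine curve).
#' @param taphonomy_enabled thin open-air dates by the survival function.
#' @param taphonomy [taphonomic_model()] used when enabled.
#' @param marine_fraction_of_dates proportion of dates on the marine axis.
#' @param dup_context_fraction proportion of dates duplicated into an
#'   existing context (exercises pooling).
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return An object of class `synthetic_scenario`.
#' @seealso [scenario_preset()], [simulate_dataset()]
#' @export
synthetic_scenario <- function(true_model, window = c(18000, 7500),
                               n_dates = 500, site_count = 100,
                               episodes_per_site = 5,
                               region_mix = c(Cantabrian = 0.25, Ebro = 0.15,
                                              Atlantic = 0.2,
                                              Mediterranean = 0.3,
                                              Interior = 0.1),
                               site_type_mix = c(open_air = 0.3,
                                                 cave_rockshelter = 0.6,
                                                 unknown = 0.1),
                               error_dist = list(meanlog = log(60),
                                                 sdlog = 0.4,
                                                 min = 20, cap = 199),
                               curve = list(kind = "wiggly",
                                            wiggle_amplitude = 30,
                                            wiggle_period = 800, sigma = 30,
                                            marine_offset = 400),
                               taphonomy_enabled = TRUE,
                               taphonomy = taphonomic_model(),
                               marine_fraction_of_dates = 0,
                               dup_context_fraction = 0,
                               seed = 1L) {
  if (n_dates < 1L) stop_value("n_dates must be at least 1")
  if (abs(sum(region_mix) - 1) > 1e-8 || abs(sum(site_type_mix) - 1) > 1e-8)
    stop_value("region_mix and site_type_mix must each sum to 1")
  structure(list(true_model = true_model, window = window, n_dates = n_dates,
                 site_count = site_count,
                 episodes_per_site = episodes_per_site,
                 region_mix = region_mix,
                 site_type_mix = site_type_mix, error_dist = error_dist,
                 curve = curve, taphonomy_enabled = taphonomy_enabled,
                 taphonomy = taphonomy,
                 marine_fraction_of_dates = marine_fraction_of_dates,
                 dup_context_fraction = dup_context_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Built-in scenario presets
#'
#' One preset per candidate growth model, with parameters of the magnitudes
#' seen in Final Pleistocene/Early Holocene forager records: phase-1
#' exponential growth near 0.04 %/yr, a post-interstadial decline starting
#' near -0.79 %/yr and levelling off, and an Early Holocene logistic
#' recovery whose annual rate peaks near 0.22 %/yr.  `"model_f_study"` is
#' the full three-phase study-scale scenario with breakpoints at 12,780 and
#' 10,120 cal BP.
#'
#' @param name preset name: `"model_a"` .. `"model_f"`, or `"model_f_study"`.
#' @param ... overrides passed on to [synthetic_scenario()].
#' @return A [synthetic_scenario()].
#' @export
scenario_preset <- function(name = "model_f_study", ...) {
  t0 <- 18000
  r1 <- log(1 + 0.0411 / 100)            # phase-1 rate, 0.0411 %/yr
  tau_bp <- c(5220, 7880)                # 12,780 and 10,120 cal BP
  y1 <- exp(r1 * tau_bp[1L])
  phase2 <- c(a = 0.5 * y1, b = 0.0158, c = 0.5 * y1)  # initial rate -0.79 %/yr
  y2 <- unname(phase2["c"])
  phase3_log <- c(A = y2, x0 = 401, s = 77.89, c = y2) # peak rate ~0.22 %/yr
  tm <- switch(name,
    model_a = list(phases = "exponential",
                   params = list(c(alpha = 1, rate = 2e-4)),
                   tau_breaks = numeric(), t0 = t0),
    model_b = list(phases = "logistic",
                   params = list(c(A = 8, x0 = 5500, s = 900, c = 1)),
                   tau_breaks = numeric(), t0 = t0),
    model_c = list(phases = c("exponential", "exponential"),
                   params = list(c(alpha = 1, rate = r1),
                                 c(alpha = 0.45 * y1, rate = 5e-5)),
                   tau_breaks = tau_bp[1L], t0 = t0),
    model_d = list(phases = c("exponential", "logistic"),
                   params = list(c(alpha = 1, rate = r1),
                                 c(A = 0.5 * y1, x0 = 2800, s = 250,
                                   c = 0.45 * y1)),
                   tau_breaks = tau_bp[1L], t0 = t0),
    model_e = list(phases = c("exponential", "decay_to_limit", "exponential"),
                   params = list(c(alpha = 1, rate = r1), phase2,
                                 c(alpha = y2, rate = 3e-4)),
                   tau_breaks = tau_bp, t0 = t0),
    model_f = ,
    model_f_study = list(phases = c("exponential", "decay_to_limit",
                                    "logistic"),
                         params = list(c(alpha = 1, rate = r1), phase2,
                                       phase3_log),
                         tau_breaks = tau_bp, t0 = t0),
    stop_value(sprintf("unknown preset '%s'", name)))
  synthetic_scenario(true_model = tm, ...)
}

# evaluate a scenario's true model on a calendar grid
.truth_on_grid <- function(true_model, cal_bp) {
  model_curve(true_model$phases, true_model$params, true_model$t0 - cal_bp,
              true_model$tau_breaks)
}

#' Simulate a radiocarbon dataset with known ground truth
#'
#' Draws calendar ages in proportion to the scenario's demographic curve
#' (thinned by the taphonomic survival function for dates at open-air sites
#' when enabled), back-calibrates each through the scenario curve with curve
#' noise, attaches a truncated log-normal laboratory error, and wraps each
#' determination in site/region/material/site-type/context metadata matching
#' the database schema.  A ground-truth table (true calendar age and model
#' value per date) is returned alongside, sufficient to score every
#' downstream estimator without re-simulation.
#'
#' @param scenario a [synthetic_scenario()].
#' @return A list: `dates` (data frame in the [load_dataset()] schema),
#'   `truth` (lab_id, true_cal_bp, model_value), `curve`
#'   (the atmospheric [cal_curve()]), `marine_curve` (or `NULL`) and
#'   `sites`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  cv <- scenario$curve
  curve <- make_synthetic_curve(cv$kind,
                                range = c(min(scenario$window) - 1000,
                                          max(scenario$window) + 1000),
                                wiggle_amplitude = cv$wiggle_amplitude %||% 20,
                                wiggle_period = cv$wiggle_period %||% 500,
                                sigma = cv$sigma %||% 10)
  marine_curve <- NULL
  if (scenario$marine_fraction_of_dates > 0) {
    marine_curve <- curve
    marine_curve$c14_mean <- curve$c14_mean + (cv$marine_offset %||% 400)
    marine_curve$name <- "synthetic_marine"
  }

  n <- scenario$n_dates
  grid <- seq(min(scenario$window), max(scenario$window))
  target <- .truth_on_grid(scenario$true_model, grid)
  if (any(target < 0)) stop_value("true model curve is negative in the window")
  surv <- scenario$taphonomy$survival(grid)

  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(scenario$site_count)),
    site_name = sprintf("Synthetic site %d", seq_len(scenario$site_count)),
    region = sample(names(scenario$region_mix), scenario$site_count,
                    replace = TRUE, prob = scenario$region_mix),
    site_type = sample(names(scenario$site_type_mix), scenario$site_count,
                       replace = TRUE, prob = scenario$site_type_mix),
    latitude = round(stats::runif(scenario$site_count, 36, 43.5), 4),
    longitude = round(stats::runif(scenario$site_count, -9.3, 3.2), 4),
    stringsAsFactors = FALSE)

  # Dates are assigned to sites in temporally contiguous blocks: real sites
  # are occupied over limited episodes, which is what makes per-site binning
  # meaningful.  Drawing ages first and then blocking preserves the marginal
  # age distribution exactly.
  site_idx <- sample.int(scenario$site_count, n, replace = TRUE)
  open_air <- sites$site_type[site_idx] == "open_air"
  ages <- integer(n)
  if (scenario$taphonomy_enabled && any(open_air))
    ages[open_air] <- sample(grid, sum(open_air), replace = TRUE,
                             prob = target * surv)
  if (any(!open_air) || !scenario$taphonomy_enabled) {
    i <- if (scenario$taphonomy_enabled) !open_air else rep(TRUE, n)
    ages[i] <- sample(grid, sum(i), replace = TRUE, prob = target)
  }
  for (tp in unique(sites$site_type)) {
    d_i <- which(sites$site_type[site_idx] == tp)
    s_i <- which(sites$site_type == tp)
    if (length(d_i) < 2L || length(s_i) < 2L) next
    n_epi <- max(1L, round(length(s_i) * scenario$episodes_per_site))
    sizes <- as.vector(stats::rmultinom(1L, length(d_i), rep(1, n_epi)))
    episode_site <- sample(s_i, n_epi, replace = TRUE)
    site_idx[d_i[order(ages[d_i])]] <- rep(episode_site, times = sizes)
  }
  open_air <- sites$site_type[site_idx] == "open_air"

  # duplicated contexts are repeat determinations of one dated event: they
  # share the true calendar age (and site) of the date they duplicate
  context_id <- sprintf("ctx_%05d", seq_len(n))
  if (scenario$dup_context_fraction > 0) {
    ndup <- round(n * scenario$dup_context_fraction)
    if (ndup > 0) {
      dup_from <- sample.int(n, ndup, replace = TRUE)
      dup_to <- sample.int(n, ndup, replace = TRUE)
      keep <- dup_from != dup_to
      context_id[dup_to[keep]] <- context_id[dup_from[keep]]
      site_idx[dup_to[keep]] <- site_idx[dup_from[keep]]
      ages[dup_to[keep]] <- ages[dup_from[keep]]
    }
  }

  is_marine <- stats::runif(n) < scenario$marine_fraction_of_dates
  ed <- scenario$error_dist
  errs <- pmin(ed$cap, pmax(ed$min,
                            round(stats::rlnorm(n, ed$meanlog, ed$sdlog))))
  c14 <- numeric(n)
  if (any(!is_marine)) c14[!is_marine] <- back_calibrate(ages[!is_marine], curve)
  if (any(is_marine)) c14[is_marine] <- back_calibrate(ages[is_marine],
                                                       marine_curve)
  c14 <- round(c14 + stats::rnorm(n, 0, errs))

  material <- ifelse(stats::runif(n) < 0.7,
                     sample(c("bone collagen", "seed", "fruit"), n, TRUE),
                     "charcoal")
  material_class <- ifelse(material == "charcoal", "long_lived", "short_lived")

  dates <- data.frame(
    lab_id = sprintf("LAB-%05d", seq_len(n)),
    site_id = sites$site_id[site_idx],
    site_name = sites$site_name[site_idx],
    region = sites$region[site_idx],
    latitude = sites$latitude[site_idx],
    longitude = sites$longitude[site_idx],
    site_type = sites$site_type[site_idx],
    material = material,
    material_class = material_class,
    aggregate_consistent = TRUE,
    c14_age_bp = c14,
    c14_error = errs,
    d13c = round(ifelse(is_marine, stats::rnorm(n, -13, 0.6),
                        stats::rnorm(n, -20.5, 0.8)), 2),
    curve_class = ifelse(is_marine, "marine", "atmospheric"),
    context_id = context_id,
    stringsAsFactors = FALSE)

  truth <- data.frame(lab_id = dates$lab_id, true_cal_bp = ages,
                      model_value = .truth_on_grid(scenario$true_model, ages),
                      stringsAsFactors = FALSE)
  list(dates = dates, truth = truth, curve = curve,
       marine_curve = marine_curve, sites = sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a proxy series with a target rank correlation
#'
#' Gaussian-copula construction: the reference curve's normal scores are
#' mixed with independent Gaussian noise so that the expected Spearman
#' correlation with the reference equals `coupling` (the mixing weight is
#' the Pearson correlation \eqn{2\sin(\pi\rho_s/6)} that yields the desired
#' Spearman value for a bivariate Gaussian copula).
#'
#' @param grid calendar grid.
#' @param reference reference values on `grid` (for example an SPD density).
#' @param coupling target Spearman correlation in `[-1, 1]`.
#' @param noise_sd additional measurement noise (in output units) added after
#'   coupling; lowers the realised correlation slightly.
#' @param seed optional integer seed.
#' @param label series label.
#' @return A [proxy_series()] on `grid`.
#' @export
simulate_proxy <- function(grid, reference, coupling, noise_sd = 0,
                           seed = NULL, label = "synthetic_proxy") {
  if (abs(coupling) > 1) stop_value("coupling must be in [-1, 1]")
  if (length(reference) != length(grid))
    stop_value("reference must be on the grid")
  if (!is.null(seed)) set.seed(seed)
  n <- length(grid)
  z_ref <- stats::qnorm((rank(reference, ties.method = "average") - 0.375) /
                          (n + 0.25))
  rho_p <- 2 * sin(pi * coupling / 6)
  z <- rho_p * z_ref + sqrt(max(0, 1 - rho_p^2)) * stats::rnorm(n)
  v <- z + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  proxy_series(grid, v, label)
}
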