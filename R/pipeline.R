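#' Pipeline configuration
#'
#' Builds (and validates) the configuration object that drives
#' [run_stage()].  Settings can come from a YAML file, from `...` overrides,
#' or both (overrides win).  The analysis window must lie strictly inside
#' the build window: the broader build window absorbs calibration edge
#' effects before any model sees the data.
#'
#' @param path optional YAML file.
#' @param ... named overrides of top-level entries (lists are merged one
#'   level deep).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    paths = list(dataset = "dataset.csv", truth = "truth.csv",
                 curve_atmospheric = "curve_atm.14c",
                 curve_marine = NULL, proxies = NULL,
                 output_dir = "paleodem_out"),
    windows = list(build = c(18000, 7500), analysis = c(16600, 8000)),
    filter = list(max_error = 200, excluded_classes = "excluded_class"),
    bin_width = 200,
    bootstrap = list(n_iter = 1000),
    null = list(n_sim = 1000),
    ci_level = 95.4,
    models = list(ids = c("A", "B", "C", "D", "E", "F"),
                  breakpoints = c(12900, 10200), half_width = 150,
                  min_phase = 2000, scan = "coarse", thin = 1),
    correlate = list(coupling = NA),
    scenario = list(preset = "model_f_study", n_dates = 500,
                    marine_fraction_of_dates = 0),
    toggles = list(taphonomy = TRUE, scaling = FALSE),
    seed = 1L)
  if (!is.null(path)) cfg <- .merge_cfg(cfg, yaml::read_yaml(path))
  cfg <- .merge_cfg(cfg, list(...))
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.merge_cfg <- function(base, upd) {
  for (k in names(upd)) {
    if (is.list(base[[k]]) && is.list(upd[[k]]))
      base[[k]] <- utils::modifyList(base[[k]], upd[[k]])
    else base[[k]] <- upd[[k]]
  }
  base
}

.validate_config <- function(cfg) {
  bad <- character()
  b <- cfg$windows$build; a <- cfg$windows$analysis
  if (!(max(a) < max(b) && min(a) > min(b)))
    bad <- c(bad, "windows.analysis (must be strictly inside windows.build)")
  if (cfg$bootstrap$n_iter < 2) bad <- c(bad, "bootstrap.n_iter (>= 2)")
  if (cfg$null$n_sim < 2) bad <- c(bad, "null.n_sim (>= 2)")
  if (cfg$bin_width <= 0) bad <- c(bad, "bin_width (> 0)")
  if (cfg$filter$max_error <= 0) bad <- c(bad, "filter.max_error (> 0)")
  if (cfg$ci_level <= 0 || cfg$ci_level >= 100) bad <- c(bad, "ci_level")
  if (length(bad))
    stop_validation(paste0("invalid configuration keys: ",
                           paste(bad, collapse = "; ")))
  invisible(cfg)
}

.stages <- c("simulate", "prepare", "calibrate", "spd", "bootstrap",
             "test-null", "fit-models", "correlate")

# per-stage RNG stream derived from the one global seed
.stage_seed <- function(cfg, stage) {
  (as.integer(cfg$seed) + 1009L * match(stage, .stages)) %% 2147483647L
}

.cfg_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

.artifact <- function(out, name) file.path(out, name)

.require_artifacts <- function(out, files, needed_stage) {
  missing <- files[!file.exists(file.path(out, files))]
  if (length(missing))
    stop_dependency(sprintf(
      "missing artifact(s) %s; run stage '%s' first",
      paste(missing, collapse = ", "), needed_stage))
}

.write_manifest <- function(out, stage, cfg, files, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = .cfg_hash(cfg), seed = seed,
         files = files, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Executes one stage of the analysis (`simulate`, `prepare`, `calibrate`,
#' `spd`, `bootstrap`, `test-null`, `fit-models`, `correlate`) against the
#' artifacts directory, writing versioned CSV/JSON artifacts plus a manifest
#' (config hash, stage seed).  Re-running a stage with an identical
#' configuration reproduces byte-identical numerical artifacts.  A stage
#' whose upstream artifacts are missing fails with a dependency error that
#' names the stage to run first.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @param out output/artifact directory (defaults to
#'   `config$paths$output_dir`).
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_stage <- function(stage, config, out = config$paths$output_dir) {
  stage <- match.arg(stage, .stages)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- .stage_seed(config, stage)
  files <- switch(
    stage,
    "simulate" = .stage_simulate(config, out, seed),
    "prepare" = .stage_prepare(config, out),
    "calibrate" = .stage_calibrate(config, out),
    "spd" = .stage_spd(config, out),
    "bootstrap" = .stage_bootstrap(config, out, seed),
    "test-null" = .stage_testnull(config, out, seed),
    "fit-models" = .stage_fitmodels(config, out),
    "correlate" = .stage_correlate(config, out, seed))
  .write_manifest(out, stage, config, files, seed)
  invisible(file.path(out, files))
}

#' Run the full pipeline
#' @param config a [pipeline_config()].
#' @param out artifact directory.
#' @param stages stages to run, in order.
#' @return Invisibly, the artifact directory.
#' @export
run_pipeline <- function(config, out = config$paths$output_dir,
                         stages = .stages) {
  for (s in stages) run_stage(s, config, out)
  invisible(out)
}

# ----------------------------- stage bodies --------------------------------

.stage_simulate <- function(cfg, out, seed) {
  sc_args <- cfg$scenario
  preset <- sc_args$preset %||% "model_f_study"
  sc_args$preset <- NULL
  sc_args$seed <- seed
  sc_args$window <- cfg$windows$build
  scenario <- do.call(scenario_preset, c(list(name = preset), sc_args))
  sim <- simulate_dataset(scenario)
  utils::write.csv(sim$dates, .artifact(out, "dataset.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, .artifact(out, "truth.csv"), row.names = FALSE)
  write_calcurve(sim$curve, .artifact(out, "curve_atm.14c"))
  files <- c("dataset.csv", "truth.csv", "curve_atm.14c")
  if (!is.null(sim$marine_curve)) {
    write_calcurve(sim$marine_curve, .artifact(out, "curve_marine.14c"))
    files <- c(files, "curve_marine.14c")
  }
  files
}

.stage_prepare <- function(cfg, out) {
  .require_artifacts(out, "dataset.csv", "simulate")
  ds <- load_dataset(.artifact(out, "dataset.csv"))
  ds <- filter_dates(ds, cfg$filter$max_error, cfg$filter$excluded_classes)
  ds <- apply_combinations(ds)
  ds <- assign_bins(ds, cfg$bin_width)
  write_dataset(ds, .artifact(out, "filtered.csv"),
                .artifact(out, "provenance.csv"))
  c("filtered.csv", "provenance.csv")
}

.read_curves <- function(cfg, out) {
  atm <- read_calcurve(.artifact(out, "curve_atm.14c"))
  mar <- if (file.exists(.artifact(out, "curve_marine.14c")))
    read_calcurve(.artifact(out, "curve_marine.14c")) else NULL
  curve_set(atm, mar)
}

.stage_calibrate <- function(cfg, out) {
  .require_artifacts(out, c("filtered.csv", "curve_atm.14c"), "prepare")
  ds <- load_dataset(.artifact(out, "filtered.csv"))
  ds <- assign_bins(ds, cfg$bin_width)
  cal <- calibrate_dataset(ds, .read_curves(cfg, out))
  summaries <- do.call(rbind, lapply(cal$bins, function(bin)
    do.call(rbind, lapply(bin, function(d) {
      cum <- cumsum(d$mass)
      data.frame(source_id = d$source_id,
                 median_cal_bp = d$cal_bp[which.max(cum >= 0.5)],
                 support_min = min(d$cal_bp), support_max = max(d$cal_bp))
    }))))
  rownames(summaries) <- NULL
  utils::write.csv(summaries, .artifact(out, "calibrated.csv"),
                   row.names = FALSE)
  "calibrated.csv"
}

.build_components <- function(cfg, out) {
  ds <- load_dataset(.artifact(out, "filtered.csv"))
  ds <- assign_bins(ds, cfg$bin_width)
  cal <- calibrate_dataset(ds, .read_curves(cfg, out))
  tapho <- if (isTRUE(cfg$toggles$taphonomy)) taphonomic_model() else NULL
  scal <- scaling_model(enabled = isTRUE(cfg$toggles$scaling))
  comps <- build_spd_components(cal, cfg$windows$build, tapho, scal)
  list(ds = ds, cal = cal, comps = comps)
}

.stage_spd <- function(cfg, out) {
  .require_artifacts(out, "calibrated.csv", "calibrate")
  bc <- .build_components(cfg, out)
  rows <- list()
  for (cmp in c("open_air", "closed_site", "unclassified")) {
    s <- bc$comps[[cmp]]
    if (!is.null(s))
      rows[[cmp]] <- data.frame(cal_bp = s$cal_bp, density = s$density,
                                component = cmp)
  }
  utils::write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   .artifact(out, "spd_components.csv"), row.names = FALSE)
  write_spd(bc$comps$composite, .artifact(out, "spd_composite.csv"))
  c("spd_components.csv", "spd_composite.csv")
}

.read_composite <- function(out, bin_width = 200) {
  df <- utils::read.csv(.artifact(out, "spd_composite.csv"))
  bins <- utils::read.csv(.artifact(out, "filtered.csv"))
  ds <- assign_bins(load_dataset(bins), bin_width)  # bin count only
  spd_curve(df$cal_bp, df$density,
            n_dates = nrow(bins),
            n_bins = length(unique(ds$dates$bin_id)),
            component = "composite")
}

.stage_bootstrap <- function(cfg, out, seed) {
  .require_artifacts(out, c("spd_composite.csv", "filtered.csv"), "spd")
  spd <- .read_composite(out, cfg$bin_width)
  errors <- utils::read.csv(.artifact(out, "filtered.csv"))$c14_error
  curve <- read_calcurve(.artifact(out, "curve_atm.14c"))
  ens <- bootstrap_spd(spd, errors, curve, n_iter = cfg$bootstrap$n_iter,
                       seed = seed, ci_level = cfg$ci_level)
  write_ensemble(ens, .artifact(out, "bootstrap_summary.csv"))
  "bootstrap_summary.csv"
}

.stage_testnull <- function(cfg, out, seed) {
  .require_artifacts(out, c("spd_composite.csv", "bootstrap_summary.csv"),
                     "bootstrap")
  spd <- .read_composite(out, cfg$bin_width)
  errors <- utils::read.csv(.artifact(out, "filtered.csv"))$c14_error
  curve <- read_calcurve(.artifact(out, "curve_atm.14c"))
  null <- fit_exponential_null(spd)
  ens <- simulate_null(null, n_dates = spd$n_bins, errors = errors,
                       curve = curve, n_sim = cfg$null$n_sim, seed = seed,
                       ci_level = cfg$ci_level)
  dep <- find_departures(normalize_spd(spd), ens)
  p <- global_pvalue(dep$global_statistic, ens)
  utils::write.csv(dep$regions, .artifact(out, "departures.csv"),
                   row.names = FALSE)
  write_ensemble(ens, .artifact(out, "null_summary.csv"))
  jsonlite::write_json(
    list(annual_rate_percent = null$annual_rate_percent,
         rate_per_year = null$rate, fit_quality = null$fit_quality,
         global_statistic = dep$global_statistic, global_p = as.numeric(p),
         n_sim = cfg$null$n_sim, seed = seed),
    .artifact(out, "null_report.json"), auto_unbox = TRUE, digits = NA)
  c("departures.csv", "null_summary.csv", "null_report.json")
}

.stage_fitmodels <- function(cfg, out) {
  .require_artifacts(out, "bootstrap_summary.csv", "bootstrap")
  bs <- utils::read.csv(.artifact(out, "bootstrap_summary.csv"))
  proxy <- spd_curve(bs$cal_bp, bs$median, component = "composite",
                     normalized = TRUE)
  proxy <- trim_window(proxy, cfg$windows$analysis)
  m <- cfg$models
  set <- fit_growth_models(proxy, models = m$ids,
                           breakpoints = m$breakpoints,
                           half_width = m$half_width,
                           min_phase = m$min_phase, scan = m$scan,
                           thin = m$thin)
  utils::write.csv(set$ranking, .artifact(out, "model_ranking.csv"),
                   row.names = FALSE)
  best <- set$fits[[set$best]]
  gr <- growth_rate(best)
  utils::write.csv(gr, .artifact(out, "growth_rates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(model_id = best$model_id,
         breakpoints_cal_bp = best$breakpoints_cal_bp,
         parameters = lapply(best$params, as.list),
         rss = best$rss, k = best$k, aic = best$aic, sbc = best$sbc,
         phase_rates = attr(gr, "phase_rates")),
    .artifact(out, "best_model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  c("model_ranking.csv", "growth_rates.csv", "best_model.json")
}

.stage_correlate <- function(cfg, out, seed) {
  .require_artifacts(out, c("bootstrap_summary.csv", "best_model.json"),
                     "fit-models")
  spd <- .read_composite(out, cfg$bin_width)
  errors <- utils::read.csv(.artifact(out, "filtered.csv"))$c14_error
  curve <- read_calcurve(.artifact(out, "curve_atm.14c"))
  ens <- bootstrap_spd(spd, errors, curve,
                       n_iter = min(cfg$bootstrap$n_iter, 200),
                       seed = seed, ci_level = cfg$ci_level)
  best <- jsonlite::read_json(.artifact(out, "best_model.json"),
                              simplifyVector = TRUE)
  bps <- sort(unique(c(max(cfg$windows$analysis),
                       round(best$breakpoints_cal_bp),
                       min(cfg$windows$analysis))), decreasing = TRUE)
  proxies <- list()
  if (!is.null(cfg$paths$proxies)) {
    for (p in cfg$paths$proxies) proxies[[basename(p)]] <- read_proxy(p)
  } else {
    cp <- cfg$correlate$coupling
    if (is.na(cp)) cp <- 0.5
    proxies[["co_simulated"]] <- simulate_proxy(ens$cal_bp, ens$median_curve,
                                                coupling = cp, seed = seed)
  }
  rows <- list()
  for (nm in names(proxies)) {
    for (ph in seq_len(length(bps) - 1L)) {
      win <- c(bps[ph], bps[ph + 1L])
      res <- tryCatch(spearman_ensemble(ens, proxies[[nm]], win),
                      paleodem_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, proxy = nm, window_start = win[1L], window_end = win[2L],
        mean_rho = res$mean_rho, sd_rho = res$sd_rho, p = res$p,
        detrended_variance = detrended_variance(
          align_series(proxies[[nm]], ens$cal_bp), win))
    }
  }
  utils::write.csv(do.call(rbind, rows), .artifact(out, "correlation.csv"),
                   row.names = FALSE)
  "correlation.csv"
}
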