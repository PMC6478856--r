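test_that("synthetic curves have their stated forms and guard monotonicity", {
  idc <- make_synthetic_curve("identity", c(1000, 1500), sigma = 3)
  expect_equal(idc$c14_mean, idc$cal_bp)
  off <- make_synthetic_curve("linear_offset", c(1000, 1500), offset = 400,
                              sigma = 0)
  expect_equal(off$c14_mean, off$cal_bp + 400)
  expect_equal(back_calibrate(1200, off), 1600)
  wig <- make_synthetic_curve("wiggly", c(1000, 3000), wiggle_amplitude = 20,
                              wiggle_period = 500, sigma = 2)
  expect_true(all(diff(wig$c14_mean) > 0))
  expect_error(make_synthetic_curve("wiggly", c(1000, 3000),
                                    wiggle_amplitude = 200,
                                    wiggle_period = 500),
               class = "paleodem_parameter_error")
})

test_that("generated datasets pass schema validation with zero quarantines", {
  sc <- scenario_preset("model_f_study", n_dates = 200, seed = 5,
                        marine_fraction_of_dates = 0.1,
                        dup_context_fraction = 0.05)
  sim <- simulate_dataset(sc)
  expect_equal(nrow(sim$dates), 200L)
  ds <- load_dataset(sim$dates)
  expect_equal(nrow(ds$log), 0L)
  expect_equal(nrow(ds$dates), 200L)
  # all lab errors below the filter bound by construction
  expect_true(all(sim$dates$c14_error < 200))
  expect_equal(nrow(filter_dates(ds)$dates), 200L)
  # ground truth covers every date
  expect_setequal(sim$truth$lab_id, sim$dates$lab_id)
  expect_true(all(sim$truth$true_cal_bp >= 7500 &
                    sim$truth$true_cal_bp <= 18000))
})

test_that("simulation is byte-identical under a fixed seed", {
  sc <- scenario_preset("model_a", n_dates = 60, seed = 33)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(simulate_dataset(sc)$dates, f1, row.names = FALSE)
  write.csv(simulate_dataset(sc)$dates, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a flat true model yields uniform calendar ages", {
  tm <- list(phases = "exponential", params = list(c(alpha = 1, rate = 0)),
             tau_breaks = numeric(), t0 = 18000)
  sc <- synthetic_scenario(tm, n_dates = 4000, seed = 8,
                           taphonomy_enabled = FALSE)
  sim <- simulate_dataset(sc)
  ks <- suppressWarnings(ks.test(sim$truth$true_cal_bp,
                                 "punif", 7500, 18000))
  expect_gt(ks$p.value, 0.01)
})

test_that("taphonomic thinning is visible in open-air ages and correctable", {
  tm <- list(phases = "exponential", params = list(c(alpha = 1, rate = 0)),
             tau_breaks = numeric(), t0 = 18000)
  # one site per date so binning stays neutral and the comparison isolates
  # the taphonomic tilt (binning itself absorbs part of the thinning signal)
  sc <- synthetic_scenario(tm, n_dates = 3000, site_count = 3000, seed = 9,
                           site_type_mix = c(open_air = 1,
                                             cave_rockshelter = 0,
                                             unknown = 0),
                           taphonomy_enabled = TRUE)
  sim <- simulate_dataset(sc)
  # survival decreasing in age: younger half oversampled
  expect_gt(mean(sim$truth$true_cal_bp < 12750), 0.5)

  # with correction enabled the SPD gets closer to the flat truth
  ds <- assign_bins(filter_dates(load_dataset(sim$dates)), 200)
  cal <- calibrate_dataset(ds, sim$curve)
  win <- c(17000, 8500)   # interior window, away from edge taper
  corr <- build_spd_components(cal, c(18000, 7500))$composite
  raw <- build_spd_components(cal, c(18000, 7500), taphonomy = NULL)$composite
  nrm <- function(s) { s <- trim_window(s, win); s$density / mean(s$density) }
  dev_corr <- max(abs(nrm(corr) - 1))
  dev_raw <- max(abs(nrm(raw) - 1))
  expect_lt(dev_corr, dev_raw)
})

test_that("copula proxies hit their coupling targets", {
  grid <- seq(1, 1000)
  ref <- abs(cumsum(rnorm(1000))) + 1
  exact <- simulate_proxy(grid, ref, coupling = 1, seed = 10)
  expect_equal(cor(exact$value, ref, method = "spearman"), 1)
  set.seed(11)
  indep <- simulate_proxy(grid, ref, coupling = 0, seed = 11)
  expect_lt(abs(cor(indep$value, ref, method = "spearman")), 0.08)
  half <- simulate_proxy(grid, ref, coupling = 0.5, seed = 12)
  expect_lt(abs(cor(half$value, ref, method = "spearman") - 0.5), 0.06)
})

test_that("the end-to-end exponential rate is recovered from synthetic data", {
  sc <- scenario_preset("model_a", n_dates = 500, seed = 1,
                        taphonomy_enabled = FALSE)
  sim <- simulate_dataset(sc)
  ds <- assign_bins(apply_combinations(filter_dates(load_dataset(sim$dates))),
                    200)
  cal <- calibrate_dataset(ds, sim$curve)
  comps <- build_spd_components(cal, c(18000, 7500), taphonomy = NULL)
  nl <- fit_exponential_null(trim_window(comps$composite, c(16600, 8000)))
  expect_lt(abs(nl$rate - 2e-4) / 2e-4, 0.25)
})
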