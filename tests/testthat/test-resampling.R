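test_that("degenerate bootstrap of a one-year spike has a zero-width envelope", {
  cc <- identity_curve(c(1000, 2000), sigma = 0)
  grid <- seq(1200, 1800)
  dens <- numeric(length(grid)); dens[grid == 1500] <- 1
  spd <- spd_curve(grid, dens, n_bins = 1L, component = "composite",
                   normalized = TRUE)
  ens <- bootstrap_spd(spd, errors = 5, curve = cc, n_iter = 20, seed = 1)
  # every member is the same recalibrated spike
  expect_equal(ens$lower, ens$upper)
  expect_equal(max(abs(ens$members[1, ] - ens$members[20, ])), 0)
  expect_equal(ens$cal_bp[which.max(ens$median_curve)], 1500)
})

test_that("bootstrap is reproducible from its seed and respects iteration count", {
  cc <- identity_curve(c(1000, 3000), sigma = 10)
  grid <- seq(1200, 2800)
  dens <- dnorm(grid, 2000, 200); dens <- dens / sum(dens)
  spd <- spd_curve(grid, dens, n_bins = 30L, component = "composite",
                   normalized = TRUE)
  e1 <- bootstrap_spd(spd, errors = c(20, 40), curve = cc, n_iter = 10, seed = 99)
  e2 <- bootstrap_spd(spd, errors = c(20, 40), curve = cc, n_iter = 10, seed = 99)
  expect_identical(e1$members, e2$members)
  expect_error(bootstrap_spd(spd, errors = 20, curve = cc, n_iter = 1),
               class = "paleodem_value_error")
  expect_error(bootstrap_spd(spd, errors = numeric(), curve = cc, n_iter = 5),
               class = "paleodem_value_error")
})

test_that("the 95.4% envelope uses pointwise percentiles and widens with level", {
  set.seed(5)
  members <- matrix(rnorm(200 * 50), 200, 50)
  ens <- spd_ensemble(1:50, members, ci_level = 95.4)
  expect_equal(ens$lower, apply(members, 2, quantile, 0.023), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ens$upper, apply(members, 2, quantile, 0.977), tolerance = 1e-12,
               ignore_attr = TRUE)
  wider <- spd_ensemble(1:50, members, ci_level = 99)
  expect_true(all(wider$lower <= ens$lower + 1e-12))
  expect_true(all(wider$upper >= ens$upper - 1e-12))
  expect_true(all(ens$lower <= ens$median_curve & ens$median_curve <= ens$upper))
})

test_that("exponential null fitting recovers exact and flat inputs", {
  tau <- 0:6000
  y <- 0.001 * exp(2e-4 * tau)
  spd <- spd_curve(10000 - rev(tau), rev(y), component = "composite")
  nl <- fit_exponential_null(spd)
  expect_lt(abs(nl$rate - 2e-4), 1e-9)
  expect_equal(nl$fit_quality, 1, tolerance = 1e-9)
  expect_equal(nl$annual_rate_percent, 100 * (exp(2e-4) - 1), tolerance = 1e-6)
  # fitted curve reproduces the data
  expect_equal(predict(nl, spd$cal_bp), spd$density, tolerance = 1e-6)

  flat <- spd_curve(seq(4000, 9000), rep(0.3, 5001), component = "composite")
  expect_lt(abs(fit_exponential_null(flat)$rate), 1e-10)
  zero <- spd_curve(1:10 + 5000, rep(0, 10), component = "composite")
  expect_error(fit_exponential_null(zero), class = "paleodem_model_error")
})

test_that("departure regions and statistic match a brute-force scan", {
  grid <- 1001:1010
  lower <- rep(0.08, 10); upper <- rep(0.12, 10)
  members <- rbind(lower + 0.01, upper - 0.01)
  ens <- spd_ensemble(grid, members)
  ens$lower <- lower; ens$upper <- upper
  y <- c(0.09, 0.14, 0.15, 0.09, 0.05, 0.09, 0.09, 0.13, 0.09, 0.02)
  obs <- spd_curve(grid, y, component = "composite", normalized = TRUE)
  dep <- find_departures(obs, ens)
  # brute force: exceedances at 2,3 (pos), 5 (neg), 8 (pos), 10 (neg);
  # regions are reported oldest (largest cal BP) first
  expect_equal(dep$regions$sign, c("negative", "positive", "negative", "positive"))
  expect_equal(dep$regions$start, c(1010, 1008, 1005, 1003))
  expect_equal(dep$regions$end, c(1010, 1008, 1005, 1002))
  stat <- sum(pmax(0, y - upper)) + sum(pmax(0, lower - y))
  expect_equal(dep$global_statistic, stat)

  inside <- spd_curve(grid, rep(0.1, 10), component = "composite",
                      normalized = TRUE)
  dep0 <- find_departures(inside, ens)
  expect_equal(nrow(dep0$regions), 0L)
  expect_equal(dep0$global_statistic, 0)
})

test_that("the rank-based global p-value follows the +1 convention", {
  set.seed(8)
  members <- matrix(runif(999 * 20, 0, 0.1), 999, 20)
  ens <- spd_ensemble(1:20, members)
  # observed statistic of zero can never beat any simulation
  expect_equal(as.numeric(global_pvalue(0, ens)), 1)
  # observed above every simulated statistic
  expect_equal(as.numeric(global_pvalue(1e9, ens)), 1 / 1000)
})

test_that("a single constructed positive run is localised exactly", {
  grid <- 2001:2100
  members <- rbind(rep(0.009, 100), rep(0.011, 100))
  ens <- spd_ensemble(grid, members)
  y <- rep(0.010, 100)
  y[40:60] <- ens$upper[40:60] + 1e-5
  obs <- spd_curve(grid, y, component = "composite", normalized = TRUE)
  dep <- find_departures(obs, ens)
  expect_equal(nrow(dep$regions), 1L)
  expect_equal(dep$regions$sign, "positive")
  expect_equal(dep$regions$end, grid[40])
  expect_equal(dep$regions$start, grid[60])
  expect_equal(dep$global_statistic, 21e-5, tolerance = 1e-9)
})

test_that("null simulation with rate 0 brackets a flat curve on a clean curve", {
  cc <- identity_curve(c(500, 3500), sigma = 0)
  null <- structure(list(rate = 0, scale = 1, t0 = 3000,
                         annual_rate_percent = 0,
                         fit_window = c(3000, 1000), fit_quality = 1),
                    class = "exp_null")
  ens <- simulate_null(null, n_dates = 150, errors = c(20, 30), curve = cc,
                       n_sim = 60, seed = 4)
  flat <- rep(1 / length(ens$cal_bp), length(ens$cal_bp))
  inner <- ens$cal_bp > 1150 & ens$cal_bp < 2850   # away from edge taper
  expect_gt(mean(flat[inner] >= ens$lower[inner] &
                 flat[inner] <= ens$upper[inner]), 0.9)
})

test_that("simulated null dates follow the null distribution (identity curve)", {
  cc <- identity_curve(c(500, 3500), sigma = 0)
  spd <- spd_curve(seq(1000, 3000), exp(5e-4 * (3000 - seq(1000, 3000))),
                   component = "composite")
  null <- fit_exponential_null(spd)
  ens <- simulate_null(null, n_dates = 4000, errors = 15, curve = cc,
                       n_sim = 2, seed = 6)
  # the mean member should match the null density closely in distribution
  m <- colMeans(ens$members)
  target <- predict(null, ens$cal_bp); target <- target / sum(target)
  expect_lt(max(abs(cumsum(m) - cumsum(target))), 0.02)
})

test_that("marine allocation of simulated dates does not distort the envelope", {
  cc <- identity_curve(c(500, 3500), sigma = 5)
  mar <- cc; mar$c14_mean <- cc$c14_mean + 400
  spd <- spd_curve(seq(1000, 3000), rep(1, 2001), component = "composite")
  null <- fit_exponential_null(spd)
  e0 <- simulate_null(null, 100, errors = c(20, 30), curve = cc, n_sim = 50,
                      seed = 9)
  e1 <- simulate_null(null, 100, errors = c(20, 30), curve = cc, n_sim = 50,
                      seed = 9, marine = list(curve = mar, proportion = 0.3))
  # envelopes statistically indistinguishable: the median shift between the
  # two is small against the envelope's own Monte-Carlo width
  inner <- e0$cal_bp > 1150 & e0$cal_bp < 2850
  shift <- mean(abs(e0$median_curve[inner] - e1$median_curve[inner]))
  width <- mean(e0$upper[inner] - e0$lower[inner])
  expect_lt(shift, width / 4)
})

test_that("regional subsampling nulls behave at the exhaustive and minimal limits", {
  cc <- identity_curve(c(4000, 7000), sigma = 0)
  bins <- list(list(calibrate(4500, 30, cc)), list(calibrate(5000, 40, cc)),
               list(calibrate(5500, 30, cc)), list(calibrate(6000, 50, cc)))
  # region = whole record: every subsample is the full record
  full <- regional_null(bins, bins, window = c(6500, 4200), n_sim = 10, seed = 2)
  expect_equal(full$lower, full$upper)
  # single-bin regions give single-bin members
  one <- regional_null(bins[1], bins, window = c(6500, 4200), n_sim = 25, seed = 2)
  expect_true(all(abs(rowSums(one$members) - 1) < 1e-6))
  expect_error(regional_null(list(), bins, c(6500, 4200)),
               class = "paleodem_value_error")
  expect_error(regional_null(bins, bins[1:2], c(6500, 4200)),
               class = "paleodem_value_error")
})

test_that("envelope width shrinks as the regional bin count grows", {
  cc <- identity_curve(c(4000, 7000), sigma = 0)
  set.seed(31)
  pool <- lapply(1:40, function(i)
    list(calibrate(runif(1, 4300, 6700), 40, cc)))
  w <- sapply(c(5, 30), function(k) {
    ens <- regional_null(pool[1:k], pool, window = c(6500, 4200),
                         n_sim = 60, seed = 7)
    mean(ens$upper - ens$lower)
  })
  expect_lt(w[2], w[1])
})
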