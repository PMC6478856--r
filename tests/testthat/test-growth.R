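# deterministic proxy generator used across fitting tests
model_f_truth <- function(grid = seq(8000, 16600), t0 = 18000,
                          bp_cal = c(12780, 10120)) {
  r1 <- log(1 + 0.0411 / 100)
  tau_bp <- t0 - bp_cal
  y1 <- exp(r1 * tau_bp[1L]); y2 <- 0.5 * y1
  tm <- list(phases = c("exponential", "decay_to_limit", "logistic"),
             params = list(c(alpha = 1, rate = r1),
                           c(a = 0.5 * y1, b = 0.0158, c = 0.5 * y1),
                           c(A = y2, x0 = 401, s = 77.89, c = y2)),
             tau_breaks = tau_bp, t0 = t0)
  list(model = tm,
       proxy = data.frame(cal_bp = grid,
                          density = model_curve(tm$phases, tm$params,
                                                t0 - grid, tm$tau_breaks)))
}

test_that("phase forms evaluate to their intercepts, asymptotes and limits", {
  expect_equal(model_curve("exponential", list(c(alpha = 3, rate = 1e-3)), 0,
                           numeric()), 3)
  lg <- list(c(A = 2, x0 = 100, s = 10, c = 0.5))
  expect_equal(model_curve("logistic", lg, 1e6, numeric()), 2.5)
  expect_equal(model_curve("logistic", lg, -1e6, numeric()), 0.5)
  dc <- list(c(a = 4, b = 0.01, c = 0.7))
  expect_equal(model_curve("decay_to_limit", dc, 1e5, numeric()), 0.7)
  expect_equal(model_curve("decay_to_limit", dc, 0, numeric()), 4.7)
  expect_error(model_curve("logistic", list(c(A = 1)), 0, numeric()),
               class = "paleodem_spec_error")
  expect_error(growth_model_spec("Z"), class = "paleodem_spec_error")
})

test_that("fitting a proxy generated from model A is self-consistent", {
  tau <- 0:8000
  proxy <- data.frame(cal_bp = 16600 - tau, density = 2e-4 * exp(3e-4 * tau))
  fit <- fit_model(proxy, "A")
  expect_lt(fit$rss, 1e-12)
  expect_equal(unname(coef(fit)["phase1.exponential.rate"]), 3e-4,
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["phase1.exponential.alpha"]), 2e-4,
               tolerance = 1e-4)
})

test_that("model F breakpoints are recovered within the scan step on clean data", {
  tf <- model_f_truth()
  fit <- fit_model(tf$proxy, growth_model_spec("F"), thin = 5)
  expect_lte(abs(fit$breakpoints_cal_bp[1L] - 12780), 5)
  expect_lte(abs(fit$breakpoints_cal_bp[2L] - 10120), 5)
  # the exhaustive scan agrees with coarse-to-fine on this fixture
  fit_ex <- fit_model(tf$proxy, growth_model_spec("C", half_width = 60),
                      scan = "exhaustive", thin = 10)
  fit_co <- fit_model(tf$proxy, growth_model_spec("C", half_width = 60),
                      scan = "coarse", thin = 10)
  expect_equal(fit_ex$breakpoints_cal_bp, fit_co$breakpoints_cal_bp,
               tolerance = 1e-9)
  expect_equal(fit_ex$rss, fit_co$rss, tolerance = 1e-9)
})

test_that("model F ranks first on its own clean data and criteria agree", {
  tf <- model_f_truth()
  set <- fit_growth_models(tf$proxy, thin = 5)
  expect_equal(set$best, "F")
  expect_true(attr(set$ranking, "criteria_agree"))
  # nesting: more breakpoints never increase minimal RSS within a family
  rss <- setNames(set$ranking$rss, set$ranking$model_id)
  expect_lte(rss[["C"]], rss[["A"]])   # exp | exp+exp
  expect_lte(rss[["E"]], rss[["C"]])   # adds a third phase
})

test_that("information criteria penalise parameters and break ties stably", {
  mk <- function(id, rss, k, n = 100) structure(
    list(model_id = id, rss = rss, k = k, n = n,
         aic = paleodem:::.ic(rss, n, k, 2),
         sbc = paleodem:::.ic(rss, n, k, log(n)),
         breakpoints_cal_bp = numeric()), class = "growth_model_fit")
  rk <- rank_models(list(mk("A", 1, 2), mk("B", 1, 3)))
  expect_equal(rk$model_id, c("A", "B"))
  expect_true(attr(rk, "criteria_agree"))
  # identical fits: stable order by model id
  rk2 <- rank_models(list(mk("D", 2, 4), mk("C", 2, 4)))
  expect_equal(rk2$model_id, c("C", "D"))
  # a perfect fit ranks first under both criteria
  rk3 <- rank_models(list(mk("A", 0, 2), mk("B", 0.5, 3)))
  expect_equal(rk3$model_id, c("A", "B"))
  expect_equal(rk3$aic[1L], -Inf)
})

test_that("AIC and SBC can reverse a ranking even though RSS is nested", {
  # a 200-point fit where the extra parameters buy a small RSS gain:
  # AIC prefers the bigger model, SBC the smaller one
  n <- 200
  mk <- function(id, rss, k) structure(
    list(model_id = id, rss = rss, k = k, n = n,
         aic = paleodem:::.ic(rss, n, k, 2),
         sbc = paleodem:::.ic(rss, n, k, log(n)),
         breakpoints_cal_bp = numeric()), class = "growth_model_fit")
  small <- mk("A", 1.00, 2)
  big <- mk("F", 0.88, 9)     # 12% RSS gain for 7 extra parameters
  rk <- rank_models(list(small, big))
  expect_false(attr(rk, "criteria_agree"))
  expect_lt(big$aic, small$aic)
  expect_gt(big$sbc, small$sbc)
})

test_that("fits are deterministic and growth rates are scale-invariant", {
  tf <- model_f_truth()
  f1 <- fit_model(tf$proxy, "F", thin = 10)
  f2 <- fit_model(tf$proxy, "F", thin = 10)
  expect_identical(coef(f1), coef(f2))
  scaled <- tf$proxy; scaled$density <- scaled$density * 37.5
  f3 <- fit_model(scaled, "F", thin = 10)
  expect_equal(attr(growth_rate(f1), "phase_rates")$mean_rate,
               attr(growth_rate(f3), "phase_rates")$mean_rate,
               tolerance = 1e-6)
  # the RSS surface is near-flat at the optimum, so the chosen breakpoint may
  # wobble by a few grid steps under rescaling; the rates above are the
  # invariant quantity
  expect_true(all(abs(f1$breakpoints_cal_bp - f3$breakpoints_cal_bp) <= 5))
})

test_that("growth rates reduce to closed forms on simple curves", {
  tau <- 0:5000
  flat <- data.frame(cal_bp = 14000 - tau, density = rep(0.2, length(tau)))
  fit <- fit_model(flat, "A")
  gr <- growth_rate(fit)
  expect_true(all(abs(gr$rate_percent) < 1e-8, na.rm = TRUE))

  expo <- data.frame(cal_bp = 14000 - tau, density = 0.1 * exp(1e-3 * tau))
  fe <- fit_model(expo, "A")
  ge <- growth_rate(fe)
  expect_equal(mean(ge$rate_percent, na.rm = TRUE), 100 * (exp(1e-3) - 1),
               tolerance = 1e-6)
})

test_that("the decay-to-limit phase tends to stationary growth", {
  tf <- model_f_truth()
  fit <- fit_model(tf$proxy, "F", thin = 5)
  gr <- growth_rate(fit)
  ph2 <- gr[gr$cal_bp < fit$breakpoints_cal_bp[1L] &
              gr$cal_bp > fit$breakpoints_cal_bp[2L], ]
  rates <- ph2$rate_percent[!is.na(ph2$rate_percent)]
  # strongly negative at onset, ~0 at the end of the phase (old -> young)
  expect_lt(rates[1L], -0.5)
  expect_gt(rates[length(rates)], -1e-3)
  expect_lt(abs(rates[length(rates)]), 1e-2)
})

test_that("per-phase rate summaries and CIs reflect the generating model", {
  tf <- model_f_truth()
  fit <- fit_model(tf$proxy, "F", thin = 5)
  pr <- attr(growth_rate(fit), "phase_rates")
  expect_equal(pr$mean_rate[1L], 0.0411, tolerance = 1e-3)
  expect_lt(pr$min_rate[2L], -0.7)     # initial collapse rate
  expect_gt(pr$max_rate[3L], 0.2)      # logistic peak rate
  expect_lt(pr$max_rate[3L], 0.25)
  ci <- growth_rate_ci(fit, tf$proxy, bp_step = 75)
  expect_equal(nrow(ci), 3L)
  expect_true(all(ci$mean_lo <= ci$mean_hi))
  # the clean-data phase-1 rate lies inside its scan-induced band
  expect_gte(0.0411, ci$mean_lo[1L] - 1e-6)
  expect_lte(0.0411, ci$mean_hi[1L] + 1e-6)
})

test_that("undefined growth rates raise a model error", {
  tau <- 0:3000
  neg <- data.frame(cal_bp = 12000 - tau,
                    density = 1 - 2e-4 * tau)   # goes negative within window
  fit <- fit_model(neg, "A")
  fit$params[[1L]]["alpha"] <- -1
  expect_error(growth_rate(fit), class = "paleodem_model_error")
})

test_that("doubling time and fold change follow their closed forms", {
  expect_equal(doubling_time(100), 1)
  expect_equal(doubling_time(0.0411), log(2) / log(1.000411), tolerance = 1e-9)
  # functional identity: doubling time halves when log(1+r/100) doubles
  r1 <- 0.5; r2 <- 100 * (exp(2 * log(1 + r1 / 100)) - 1)
  expect_equal(doubling_time(r1) / doubling_time(r2), 2, tolerance = 1e-9)
  expect_error(doubling_time(0), class = "paleodem_value_error")

  expect_equal(fold_change(0, 5000), 1)
  expect_equal(fold_change(3, 0), 1)
  expect_equal(fold_change(0.1, 1000), 1.001^1000)
})

test_that("simulate() draws ages in proportion to the fitted curve", {
  tau <- 0:4000
  proxy <- data.frame(cal_bp = 14000 - tau, density = 0.1 * exp(4e-4 * tau))
  fit <- fit_model(proxy, "A")
  draws <- simulate(fit, nsim = 2, seed = 21, n_dates = 4000)
  expect_length(draws, 2L)
  # younger half (higher density) receives more draws
  expect_gt(mean(draws[[1L]] < 12000), 0.5)
})
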