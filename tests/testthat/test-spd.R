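cc0 <- identity_curve(c(4000, 7000), sigma = 0)

test_that("a single one-date bin reproduces its calibrated density", {
  d <- calibrate(5000, 40, cc0)
  s <- sum_probabilities(as_bins(d), window = c(7000, 4000))
  expect_equal(s$density[match(d$cal_bp, s$cal_bp)], d$mass)
  expect_equal(s$n_bins, 1L)
  expect_equal(sum(s$density), 1, tolerance = 1e-9)
})

test_that("disjoint unit-mass bins add raw mass; bins average their members", {
  d1 <- calibrate(4500, 30, cc0)
  d2 <- calibrate(6200, 30, cc0)
  s <- sum_probabilities(as_bins(d1, d2), window = c(7000, 4000))
  expect_equal(sum(s$density), 2, tolerance = 1e-9)

  # two dates in one bin carry unit weight jointly
  s2 <- sum_probabilities(as_bins(list(d1, d2)), window = c(7000, 4000))
  expect_equal(sum(s2$density), 1, tolerance = 1e-9)

  # brute-force oracle over a 3-bin mixed layout
  d3 <- calibrate(5300, 50, cc0)
  bins <- list(list(d1, d2), list(d3), list(d1, d3))
  s3 <- sum_probabilities(bins, window = c(7000, 4000))
  grid <- s3$cal_bp
  onto <- function(d) { v <- numeric(length(grid))
    v[match(d$cal_bp, grid)] <- d$mass; v }
  oracle <- (onto(d1) + onto(d2)) / 2 + onto(d3) + (onto(d1) + onto(d3)) / 2
  expect_equal(s3$density, oracle, tolerance = 1e-12)
  expect_error(sum_probabilities(list(), c(7000, 4000)),
               class = "paleodem_empty_error")
})

test_that("taphonomic correction divides by survival and preserves raw mass", {
  grid <- seq(8000, 18000)
  flat <- spd_curve(grid, rep(1, length(grid)), n_bins = 1L,
                    component = "open_air")
  m <- taphonomic_model()
  corr <- taphonomic_correct(flat, m)
  expect_equal(sum(corr$density), sum(flat$density))
  # correction factor grows with age: corrected flat SPD increases with cal_bp
  expect_true(all(diff(corr$density) > 0))
  # pointwise ratio matches direct formula evaluation up to one scale factor
  expected <- (1 / m$survival(grid))
  expect_equal(corr$density / expected,
               rep(sum(flat$density) / sum(expected), length(grid)),
               tolerance = 1e-12)
  # pointwise division: the density ratio of two ages inverts their survival ratio
  expect_equal(corr$density[grid == 12000] / corr$density[grid == 16898],
               m$survival(16898) / m$survival(12000))
})

test_that("constant survival leaves an SPD unchanged", {
  grid <- seq(9000, 12000)
  s <- spd_curve(grid, runif(length(grid)), component = "open_air")
  const <- taphonomic_model(a = 2, b = 1000, c = -1e-9)
  # c ~ 0 gives essentially constant survival
  corr <- taphonomic_correct(s, const)
  expect_equal(corr$density, s$density, tolerance = 1e-4)
})

test_that("taphonomic correction refuses non-open-air components", {
  s <- spd_curve(1:10 + 9000, rep(1, 10), component = "composite")
  expect_error(taphonomic_correct(s), class = "paleodem_value_error")
})

test_that("scaling correction is the identity when off and a power law when on", {
  grid <- seq(9000, 9100)
  s <- spd_curve(grid, seq(0.1, 0.4, length.out = 101), component = "open_air")
  expect_identical(scaling_correct(s, scaling_model(beta = 2, enabled = FALSE)),
                   s)
  expect_identical(scaling_correct(s, scaling_model(beta = 1, enabled = TRUE)),
                   s)
  on <- scaling_correct(s, scaling_model(beta = 2, enabled = TRUE))
  # density^(1/2) up to renormalisation: check the pointwise ratio pattern
  expect_equal(on$density / sqrt(s$density),
               rep((on$density / sqrt(s$density))[1L], 101), tolerance = 1e-9)
  expect_equal(sum(on$density), sum(s$density))
  expect_equal(sqrt(c(0.1, 0.4)) / sum(sqrt(s$density)) * sum(s$density),
               on$density[c(1L, 101L)], tolerance = 1e-9)
})

test_that("composition conserves raw mass and requires aligned grids", {
  grid <- seq(8000, 12000)
  a <- spd_curve(grid, rep(0.6, length(grid)), n_bins = 3L, component = "open_air")
  b <- spd_curve(grid, rep(0.3, length(grid)), n_bins = 2L, component = "closed_site")
  u <- spd_curve(grid, rep(0.1, length(grid)), n_bins = 1L, component = "unclassified")
  comp <- compose_final(a, b, u)
  expect_equal(sum(comp$density), sum(a$density) + sum(b$density) + sum(u$density),
               tolerance = 1e-9)
  expect_equal(comp$n_bins, 6L)
  # two missing components: composite equals the third
  only <- compose_final(NULL, b, NULL)
  expect_equal(only$density, b$density)
  # equal components triple
  trip <- compose_final(a, a, a)
  expect_equal(trip$density, 3 * a$density)
  short <- spd_curve(seq(8000, 11000), rep(1, 3001), component = "closed_site")
  expect_error(compose_final(a, short), class = "paleodem_alignment_error")
})

test_that("window trimming drops edges without renormalising", {
  grid <- seq(7500, 18000)
  s <- spd_curve(grid, rep(2, length(grid)), component = "composite")
  tr <- trim_window(s, c(16600, 8000))
  expect_equal(range(tr$cal_bp), c(8000, 16600))
  expect_equal(unique(tr$density), 2)
  expect_equal(trim_window(s, c(18000, 7500))$density, s$density)
  expect_error(trim_window(s, c(19000, 8000)), class = "paleodem_range_error")
})
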