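test_that("half-life/rate conversions are exact inverses and reject bad input", {
  expect_equal(rate_from_halflife(23), log(2) / 23)
  expect_equal(rate_from_halflife(20), 0.034657, tolerance = 1e-4)
  for (x in c(0.5, 9.1, 23, 120)) {
    expect_equal(halflife_from_rate(rate_from_halflife(x)), x)
  }
  expect_error(rate_from_halflife(0), "positive")
  expect_error(halflife_from_rate(-1), "positive")
})

test_that("linear schedules reproduce their half-life anchors", {
  s <- build_linear_schedule(23, 20, 160, 400)
  expect_equal(s$kd0, log(2) / 23)
  expect_equal(s$a, 2.825328e-5, tolerance = 1e-6)
  expect_equal(schedule_halflife(s, 160), 20)

  expect_equal(build_linear_schedule(23, 23, 160, 400)$a, 0)

  s91 <- build_linear_schedule(23, 9.1, 160, 400)
  expect_equal(schedule_halflife(s91, 160), 9.1)

  # decelerating schedule crossing zero within the window is rejected
  expect_error(degradation_schedule(log(2) / 23, -1e-3, c(0, 400)),
               "crosses zero")
  # but a negative acceleration that stays positive is allowed
  ok <- degradation_schedule(log(2) / 23, -1e-5, c(0, 400))
  expect_gt(schedule_rate(ok, 400), 0)
})

test_that("steady-state model stays flat and pure decay halves on schedule", {
  flat <- turnover_model(degradation_schedule(log(2) / 23, 0, c(0, 400)),
                         ks = "steady_state", p0 = 1)
  tr <- solve_abundance(flat, seq(0, 400, by = 40))
  expect_lt(max(abs(tr$abundance - 1)), 1e-9)

  decay <- turnover_model(degradation_schedule(log(2) / 23, 0, c(0, 100)),
                          ks = 0, p0 = 1)
  expect_equal(solve_abundance(decay, c(23, 46))$abundance, c(0.5, 0.25),
               tolerance = 1e-7)
})

test_that("the measured 3-min half-life change gives only a ~25% drop by 400 min", {
  m <- turnover_model(anchored_schedule(20), ks = "steady_state", p0 = 1)
  p400 <- solve_abundance(m, 400)$abundance
  decrease <- 100 * (1 - p400)
  expect_gt(decrease, 23)
  expect_lt(decrease, 27)
})

test_that("numerical solver agrees with the closed form on random models", {
  set.seed(42)
  worst <- 0
  for (i in 1:30) {
    m <- random_model()
    times <- sort(stats::runif(8, 1, 400))
    num <- solve_abundance(m, times)$abundance
    ana <- analytic_abundance(m, times)
    worst <- max(worst, max(abs(num - ana) / ana))
  }
  expect_lt(worst, 1e-6)
})

test_that("closed form reduces to the constant-rate and no-synthesis limits", {
  kd0 <- log(2) / 15
  m <- turnover_model(degradation_schedule(kd0, 0, c(0, 300)),
                      ks = 0.02, p0 = 0.5)
  t <- c(10, 80, 250)
  expect_equal(analytic_abundance(m, t),
               0.02 / kd0 + (0.5 - 0.02 / kd0) * exp(-kd0 * t),
               tolerance = 1e-9)

  m0 <- turnover_model(degradation_schedule(kd0, 1e-5, c(0, 300)),
                       ks = 0, p0 = 2)
  expect_equal(analytic_abundance(m0, t),
               2 * exp(-(kd0 * t + 1e-5 * t^2 / 2)), tolerance = 1e-9)
})

test_that("faster acceleration lowers abundance pointwise; abundance stays positive", {
  t <- seq(10, 400, by = 30)
  kd0 <- log(2) / 23
  prev <- NULL
  for (a in c(0, 1e-5, 5e-5, 2e-4)) {
    m <- turnover_model(degradation_schedule(kd0, a, c(0, 400)),
                        ks = kd0, p0 = 1)
    p <- analytic_abundance(m, t)
    expect_true(all(p > 0))
    if (!is.null(prev)) expect_true(all(p < prev))
    prev <- p
  }
})

test_that("quasi-steady state tracks ks/kd(t) and bounds the full solution", {
  m <- turnover_model(anchored_schedule(20), ks = "steady_state", p0 = 1)
  expect_equal(qss_abundance(m, 0), 1)
  expect_equal(qss_abundance(m, 400), 0.7272727, tolerance = 1e-6)

  # at a = 0 the deviation from QSS is exactly the decaying transient
  kd0 <- log(2) / 10
  m2 <- turnover_model(degradation_schedule(kd0, 0, c(0, 200)),
                       ks = 0.5 * kd0, p0 = 1)
  t <- c(20, 60, 120)
  dev <- abs(analytic_abundance(m2, t) - qss_abundance(m2, t)) /
    qss_abundance(m2, t)
  expect_equal(dev, abs(1 - 0.5) * exp(-kd0 * t) / 0.5, tolerance = 1e-8)

  # for small a the lag behind QSS shrinks with a
  lag_for <- function(a) {
    mm <- turnover_model(degradation_schedule(kd0, a, c(0, 400)),
                         ks = "steady_state")
    abs(analytic_abundance(mm, 400) - qss_abundance(mm, 400)) /
      qss_abundance(mm, 400)
  }
  expect_lt(lag_for(1e-6), lag_for(1e-5))
})

test_that("times outside the schedule window are refused", {
  m <- turnover_model(anchored_schedule(20), ks = "steady_state")
  expect_error(solve_abundance(m, c(100, 500)), "window")
  expect_error(analytic_abundance(m, -5), "window")
})

test_that("time/OD maps interpolate monotonically and never extrapolate", {
  map <- time_od_map(c(0, 160, 400), c(0.4, 1.0, 1.5))
  expect_equal(od_at_time(map, 160), 1.0)
  expect_equal(od_at_time(map, 80), 0.7)
  expect_equal(time_at_od(map, 1.25), 280)
  expect_error(od_at_time(map, 500), "outside")
  expect_error(time_at_od(map, 0.2), "outside")
  expect_error(time_od_map(c(0, 100), c(1.0, 0.4)), "increasing")
})
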