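test_that("the relative least-squares objective matches direct summation", {
  sched <- anchored_schedule(20)
  m <- turnover_model(sched, ks = "steady_state")

  # model scored against its own noise-free output is a perfect fit
  t <- seq(0, 400, by = 80)
  self <- abundance_series(t, analytic_abundance(m, t))
  expect_equal(relative_lsq_objective(m, self), 0, tolerance = 1e-20)

  # single point at 1.1 vs 1.0 contributes (0.1/1.0)^2
  one <- abundance_series(0, 1)
  m11 <- turnover_model(degradation_schedule(log(2) / 23, 0, c(0, 10)),
                        ks = 0, p0 = 1.1)
  expect_equal(relative_lsq_objective(m11, one), 0.01)

  # brute-force loop oracle on random observations
  set.seed(11)
  for (i in 1:5) {
    obs <- abundance_series(sort(stats::runif(6, 0, 400)),
                            stats::runif(6, 0.1, 2))
    pm <- analytic_abundance(m, obs$time_min)
    oracle <- 0
    for (j in seq_len(6)) {
      oracle <- oracle + ((pm[j] - obs$abundance[j]) / obs$abundance[j])^2
    }
    expect_equal(relative_lsq_objective(m, obs), oracle, tolerance = 1e-12)
    log_oracle <- sum((log(pm) - log(obs$abundance))^2)
    expect_equal(relative_lsq_objective(m, obs, objective = "log"),
                 log_oracle, tolerance = 1e-12)
  }
})

test_that("noise-free self-generated data returns the generating parameters", {
  sched <- anchored_schedule(9.1)
  truth <- turnover_model(sched, ks = "steady_state")
  obs <- steady_state_series(sched)
  fit <- fit_degradation_acceleration(obs, halflife_t0 = 23)
  expect_equal(fit$halflife_at(160), 9.1, tolerance = 0.01)
  expect_lt(abs(fit$ks - truth$ks) / truth$ks, 1e-3)
  expect_lt(abs(fit$a - sched$a) / sched$a, 1e-3)
  expect_lt(fit$objective, 1e-8)
})

test_that("flat abundance data yield the steady-state synthesis rate and a = 0", {
  flat <- abundance_series(c(0, 100, 200, 300, 400), rep(1, 5))
  fit <- fit_degradation_acceleration(flat, halflife_t0 = 23)
  expect_equal(fit$ks, log(2) / 23, tolerance = 1e-4)
  expect_equal(fit$a, 0, tolerance = 1e-8)
})

test_that("fitted schedules keep the degradation rate positive on the window", {
  set.seed(3)
  for (i in 1:3) {
    t <- seq(0, 400, by = 100)
    obs <- abundance_series(t, exp(-0.004 * t) * stats::runif(5, 0.9, 1.1))
    fit <- fit_degradation_acceleration(obs, halflife_t0 = 23)
    expect_true(all(schedule_rate(fit$schedule, seq(0, 400, by = 20)) > 0))
  }
})

test_that("the objective has its minimum near the truth on a parameter grid", {
  sched <- anchored_schedule(9.1)
  truth <- turnover_model(sched, ks = "steady_state")
  obs <- steady_state_series(sched, times = seq(0, 400, by = 100))
  ks_grid <- truth$ks * seq(0.5, 1.5, length.out = 9)
  a_grid <- sched$a * seq(0.5, 1.5, length.out = 9)
  vals <- outer(ks_grid, a_grid, Vectorize(function(ks, a) {
    m <- turnover_model(degradation_schedule(sched$kd0, a, c(0, 400)),
                        ks = ks)
    relative_lsq_objective(m, obs)
  }))
  best <- which(vals == min(vals), arr.ind = TRUE)
  expect_equal(ks_grid[best[1]], truth$ks, tolerance = 0.07)
  expect_equal(a_grid[best[2]], sched$a, tolerance = 0.07)
})

test_that("noisy data recover the steep half-life within 15% most of the time", {
  sched <- anchored_schedule(9.1)
  ok <- 0; n <- 20
  for (i in seq_len(n)) {
    obs <- generate_abundance_course(sched, ks = log(2) / 23,
                                     sample_times = seq(0, 400, by = 50),
                                     noise = noise_spec(0.1, 500 + i),
                                     n_replicates = 2)
    fit <- fit_degradation_acceleration(obs, halflife_t0 = 23)
    if (abs(fit$halflife_at(160) - 9.1) / 9.1 < 0.15) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n)
})

test_that("scenario curves reproduce the modest-vs-steep degradation contrast", {
  obs <- abundance_series(seq(0, 400, by = 50),
                          rep(1, 9))  # grid carrier only
  scen <- predict_scenarios(obs, list(
    measured = anchored_schedule(20),
    constant = build_linear_schedule(23, 23, 160, 400),
    best_fit = anchored_schedule(9.1)))

  # a 23 -> 20 min half-life change costs only ~25% of the protein
  p400 <- scen$measured$abundance[scen$measured$time_min == 400]
  expect_lt(abs((1 - p400) - 0.25), 0.02)

  # unchanged half-life leaves abundance flat
  expect_lt(max(abs(scen$constant$abundance - 1)), 1e-6)

  # the steep best-fit scenario lies strictly below the measured one
  later <- scen$measured$time_min > 0
  expect_true(all(scen$best_fit$abundance[later] <
                  scen$measured$abundance[later]))
})
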