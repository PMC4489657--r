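# shared fixtures: the reference degradation schedules and noise-free
# self-generated data sets used across test files

anchored_schedule <- function(hl1 = 20) build_linear_schedule(23, hl1, 160, 400)

# noise-free abundance course self-generated from a steady-state model
steady_state_series <- function(schedule, times = seq(0, 400, by = 50)) {
  m <- turnover_model(schedule, ks = "steady_state", p0 = 1)
  tr <- solve_abundance(m, times)
  abundance_series(tr$time_min, tr$abundance)
}

# random turnover models with kd positive over [0, 400]
random_model <- function() {
  hl0 <- stats::runif(1, 5, 60)
  kd0 <- rate_from_halflife(hl0)
  a <- stats::runif(1, -0.9 * kd0 / 400, 3e-4)
  ks <- stats::runif(1, 0, 2 * kd0)
  p0 <- stats::runif(1, 0.2, 2)
  turnover_model(degradation_schedule(kd0, a, c(0, 400)), ks = ks, p0 = p0)
}
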