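test_that("the global slope is the OLS slope over included points", {
  t <- c(0, 100, 200, 300)
  lin <- abundance_series(t, 1 - 0.002 * t)
  expect_equal(fit_global_slope(lin), -0.002, tolerance = 1e-12)

  flat <- abundance_series(t, rep(0.8, 4))
  expect_equal(fit_global_slope(flat), 0)

  # exclusion changes the slope exactly as the normal equations say
  with_on <- abundance_series(c(t, 1440), c(1 - 0.002 * t, 0.05),
                              label = c(rep("", 4), "overnight"))
  ols <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  expect_equal(fit_global_slope(with_on, exclude_labels = "overnight"),
               ols(t, 1 - 0.002 * t))
  expect_equal(fit_global_slope(with_on, exclude_labels = character(0)),
               ols(c(t, 1440), c(1 - 0.002 * t, 0.05)))
})

test_that("half-life assignment follows the two-epoch rule and accepts overrides", {
  s4 <- abundance_series(c(0, 100, 200, 300), rep(1, 4))
  expect_equal(assign_halflives(s4), c(23, 23, 20, 20))
  expect_equal(assign_halflives(s4, 48, 13), c(48, 48, 13, 13))
  s5 <- abundance_series(c(0, 100, 200, 300, 400), rep(1, 5))
  expect_equal(assign_halflives(s5), c(23, 23, 23, 20, 20))
  expect_equal(assign_halflives(s4, explicit = c(30, 25, 20, 15)),
               c(30, 25, 20, 15))
  expect_error(assign_halflives(s4, explicit = c(30, 25)), "length")
})

test_that("point-wise synthesis follows ks = dP/dt + kd P and normalizes to 1", {
  # steady state: constant abundance, zero slope, constant kd
  s <- abundance_series(c(0, 100, 200, 300), rep(1, 4))
  prof <- infer_synthesis_pointwise(s, halflives = rep(23, 4))
  expect_equal(prof$ks_raw, rep(log(2) / 23, 4), tolerance = 1e-12)
  expect_equal(prof$ks_norm, rep(1, 4))

  # exactly linear decline with the two-epoch half-life assignment
  t <- c(0, 100, 200, 300)
  lin <- abundance_series(t, 1 - 0.002 * t)
  prof2 <- infer_synthesis_pointwise(lin, halflives = c(23, 23, 20, 20))
  expect_equal(prof2$ks_raw[1], -0.002 + log(2) / 23, tolerance = 1e-9)
  expect_equal(prof2$ks_raw[4], -0.002 + log(2) / 20 * 0.4, tolerance = 1e-9)
  expect_equal(prof2$ks_raw[1] / prof2$ks_raw[4], 2.3718, tolerance = 1e-4)
  expect_equal(prof2$ks_norm[1], 1)
})

test_that("a near-steady trajectory with matching half-lives gives a flat profile", {
  kd0 <- log(2) / 23
  m <- turnover_model(degradation_schedule(kd0, 0, c(0, 400)), ks = kd0)
  tr <- solve_abundance(m, c(0, 130, 270, 400))
  s <- abundance_series(tr$time_min, tr$abundance)
  prof <- infer_synthesis_pointwise(s, halflives = rep(23, 4))
  expect_lt(max(abs(prof$ks_norm - 1)), 0.02)
})

test_that("negative inferred rates are retained with a warning, not clipped", {
  t <- c(0, 50, 100, 150)
  steep <- abundance_series(t, c(1, 0.5, 0.2, 0.05))
  expect_warning(prof <- infer_synthesis_pointwise(
    steep, halflives = rep(23, 4)), "negative")
  expect_true(any(prof$ks_raw < 0))
})

test_that("translation rates divide synthesis by matched mRNA levels", {
  t <- c(0, 100, 200, 300)
  s <- abundance_series(t, rep(1, 4), od600 = c(0.4, 0.8, 1.2, 1.4))
  prof <- infer_synthesis_pointwise(s, halflives = rep(23, 4))

  m_flat <- data.frame(od600 = c(0.4, 0.8, 1.2, 1.4), rel_expr = rep(1, 4))
  tr <- translation_rates(prof, m_flat)
  expect_equal(tr$rate_norm, prof$ks_norm)

  # a synthesis profile ending at 5% against 65% mRNA gives 7.69%
  prof2 <- prof
  prof2$ks_norm <- c(1, 0.6, 0.2, 0.05)
  m2 <- data.frame(od600 = c(0.4, 0.8, 1.2, 1.4),
                   rel_expr = c(1, 0.9, 0.8, 0.65))
  tr2 <- translation_rates(prof2, m2)
  expect_equal(tr2$rate_norm[4], 0.05 / 0.65, tolerance = 1e-9)

  # matching is by nearest OD within tolerance; unmatched points fail loudly
  m_far <- data.frame(od600 = c(0.4, 0.8), rel_expr = c(1, 0.9))
  expect_error(translation_rates(prof, m_far), "no mRNA sample")
})

test_that("the generator-to-inference round trip recovers a 20-fold decline", {
  sc <- default_scenario(cv_densitometry = 0, sd_ct = 0)
  g <- generate_scenario(sc, seed = 11)
  synth <- infer_synthesis_pointwise(
    g$abundance, halflives = c(23, 23, 20, 20))
  terminal <- synth$ks_norm[nrow(synth)]
  expect_equal(terminal, g$truth$terminal_synthesis_fraction,
               tolerance = 0.05)
  expr <- delta_delta_ct(g$ct, target = "dnaA", reference = "16S",
                         calibrator = "od0.4")
  tr <- translation_rates(synth, expr)
  expect_equal(tr$rate_norm[nrow(tr)], g$truth$terminal_translation_fraction,
               tolerance = 0.05)
})
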