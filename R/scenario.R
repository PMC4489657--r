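#' Default simulation scenario
#'
#' The study conditions emulated by the synthetic generators: a culture at
#' OD600 0.4 at t = 0 growing logistically to a stationary plateau of 1.5
#' (OD 1.0 at 160 min); protein half-life 23 min in exponential phase and
#' 20 min from the onset of stationary phase; densitometry sampling at
#' OD600 0.4, 0.8, 1.2 and 1.4 plus an overnight sample; chase assays at
#' the two half-life conditions; qPCR at ODs 0.2-1.4 with target mRNA never
#' falling below 65% of its exponential-phase level; and a point-wise
#' synthesis rate that declines 20-fold across the growth curve.
#'
#' The synthesis profile is constructed so that the relative abundance
#' declines linearly from 1 to the level at which the point-wise synthesis
#' rate has dropped exactly `synthesis_fold`-fold (see the methods
#' vignette); with the default 20-fold this terminal abundance is ~0.114,
#' i.e. an ~89% drop, matching the regime the estimator is designed for.
#'
#' @param synthesis_fold Fold decrease of the point-wise synthesis rate
#'   between the first and last densitometry sample (default 20).
#' @param cv_densitometry CV of multiplicative densitometry noise
#'   (default 0.1).
#' @param sd_ct Technical qPCR jitter SD in cycles (default 0.2).
#' @param n_replicates Densitometry/chase replicates (default 2 and 3).
#' @return A list of scenario parameters consumed by
#'   [generate_scenario()].
#' @export
default_scenario <- function(synthesis_fold = 20, cv_densitometry = 0.1,
                             sd_ct = 0.2, n_replicates = 2L) {
  growth <- growth_model()
  sample_ods <- c(0.4, 0.8, 1.2, 1.4)
  sample_times <- growth_time_at_od(growth, sample_ods)
  list(
    growth = growth,
    halflife_t0 = 23, halflife_t1 = 20, t1 = 160,
    sample_ods = sample_ods, sample_times = sample_times,
    overnight_time = 1440, overnight_abundance = 0.05,
    synthesis_fold = synthesis_fold,
    mrna_ods = c(0.2, 0.4, 0.8, 1.2, 1.4),
    mrna_rel = c(1.05, 1, 0.9, 0.75, 0.65),
    mrna_calibrator = "od0.4",
    chase_times = seq(0, 30, by = 10),
    cv_densitometry = cv_densitometry, sd_ct = sd_ct,
    n_replicates = as.integer(n_replicates),
    n_chase_replicates = 3L)
}

# terminal abundance of a linear decline P(t) = 1 + s t over [0, T] such
# that the point-wise synthesis rate ks(t) = s + kd(t) P(t) drops exactly
# `fold`-fold between t = 0 and t = T, with kd0/kdT the anchor rates.
linear_decline_terminal <- function(fold, T, kd0, kdT) {
  (kd0 / fold + (1 - 1 / fold) / T) / ((1 - 1 / fold) / T + kdT)
}

#' Generate the full set of synthetic input tables for a scenario
#'
#' Produces the four tables the pipeline consumes — abundance course, chase
#' assays at both half-life conditions, qPCR Ct table and growth curve —
#' together with the generating truth, all seeded and reproducible.  With
#' `dir` set, tidy CSVs plus a `truth.json` are written there.
#'
#' The abundance course is forward-solved from the turnover equation with
#' a step degradation schedule (half-life `halflife_t0` before `t1`,
#' `halflife_t1` after) and the continuous synthesis profile
#' `ks(t) = s + kd(t) P(t)` implied by a linear abundance decline; the
#' point-wise estimator is exactly self-consistent with this construction,
#' so the recorded truth is recoverable up to noise.
#'
#' @param scenario A scenario list from [default_scenario()].
#' @param seed Integer master seed; sub-seeds for the individual generators
#'   are derived from it.
#' @param dir Optional output directory for CSVs and `truth.json`.
#' @return A list with `abundance` (an [abundance_series()]), `chase` (a
#'   [chase_course()] covering both conditions), `ct` (a [ct_table()]),
#'   `growth` (data.frame), and `truth` (generating parameters).
#' @export
generate_scenario <- function(scenario = default_scenario(), seed = 1L,
                              dir = NULL) {
  seed <- as.integer(seed)
  kd0 <- rate_from_halflife(scenario$halflife_t0)
  kd1 <- rate_from_halflife(scenario$halflife_t1)
  kd_fun <- function(t) ifelse(t < scenario$t1, kd0, kd1)
  T_end <- max(scenario$sample_times)
  p_end <- linear_decline_terminal(scenario$synthesis_fold, T_end, kd0, kd1)
  s <- (p_end - 1) / T_end
  ks_fun <- function(t) s + kd_fun(t) * (1 + s * t)

  gmap <- generate_growth_curve(scenario$growth,
                                seq(0, ceiling(T_end), by = 10))

  ab <- generate_abundance_course(
    schedule = kd_fun, ks = ks_fun,
    sample_times = scenario$sample_times, p0 = 1,
    noise = noise_spec(scenario$cv_densitometry, seed),
    n_replicates = scenario$n_replicates)
  ab_df <- data.frame(time_min = ab$time_min,
                      od600 = scenario$sample_ods,
                      abundance = ab$abundance,
                      label = "")
  # overnight sample: long-stationary band, excluded from all fits
  ab_df <- rbind(ab_df, data.frame(
    time_min = scenario$overnight_time, od600 = max(scenario$sample_ods),
    abundance = scenario$overnight_abundance, label = "overnight"))
  series <- as_abundance_series(ab_df)

  chase0 <- generate_chase_course(
    scenario$halflife_t0, scenario$chase_times,
    noise = noise_spec(scenario$cv_densitometry, seed + 1L),
    n_replicates = scenario$n_chase_replicates, condition = "exponential")
  chase1 <- generate_chase_course(
    scenario$halflife_t1, scenario$chase_times,
    noise = noise_spec(scenario$cv_densitometry, seed + 2L),
    n_replicates = scenario$n_chase_replicates,
    condition = "stationary_onset")
  chase <- rbind(chase0, chase1)
  class(chase) <- c("chase_course", "data.frame")

  mrna_truth <- scenario$mrna_rel /
    scenario$mrna_rel[scenario$mrna_ods == 0.4]
  names(mrna_truth) <- paste0("od", scenario$mrna_ods)
  ct <- generate_ct_table(mrna_truth, target = "dnaA",
                          base_ct = 20, sd_ct = scenario$sd_ct,
                          od600 = stats::setNames(scenario$mrna_ods,
                                                  names(mrna_truth)),
                          seed = seed + 3L)

  # truth: point-wise synthesis at the sample times and its terminal
  # fraction; translation truth divides by the mRNA level at matched ODs
  ks_points <- ks_fun(scenario$sample_times)
  m_at_protein <- mrna_truth[paste0("od", scenario$sample_ods)]
  trans_points <- (ks_points / ks_points[1]) / m_at_protein
  truth <- list(
    halflife_t0 = scenario$halflife_t0,
    halflife_t1 = scenario$halflife_t1,
    synthesis_fold = scenario$synthesis_fold,
    terminal_synthesis_fraction = 1 / scenario$synthesis_fold,
    terminal_translation_fraction =
      unname(trans_points[length(trans_points)] / trans_points[1]),
    terminal_abundance = p_end,
    abundance_slope = s,
    ks_points = unname(ks_points),
    mrna = as.list(mrna_truth),
    seed = seed)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ab_df, file.path(dir, "abundance.csv"))
    write_table(as.data.frame(chase), file.path(dir, "chase.csv"))
    write_table(as.data.frame(ct), file.path(dir, "qpcr.csv"))
    write_table(gmap$curve, file.path(dir, "growth.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(abundance = series, chase = chase, ct = ct, growth = gmap$curve,
       truth = truth)
}
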