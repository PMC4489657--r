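#' Logistic growth model for a batch culture
#'
#' OD600 follows `OD(t) = K / (1 + ((K - od0)/od0) exp(-r t))`: exponential
#' at low density, arresting at the carrying capacity `K` as nutrients run
#' out.  The default parameters place the culture at OD 0.4 at t = 0 and
#' OD 1.0 at t = 160 min, approaching a stationary plateau of 1.5 —
#' the growth-curve anchors used throughout the package.
#'
#' @param od0 OD600 at t = 0 (0 < od0 < K).
#' @param K Carrying capacity (stationary-phase OD600).
#' @param r Growth constant, min^-1.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(od0 = 0.4, K = 1.5, r = log(5.5) / 160) {
  stopifnot(od0 > 0, K > od0, r > 0)
  structure(list(od0 = od0, K = K, r = r), class = "growth_model")
}

#' Evaluate and sample a growth curve
#'
#' `growth_od()` evaluates the logistic curve; `growth_time_at_od()` inverts
#' it; `generate_growth_curve()` samples it on a time grid and returns both
#' the OD series and the induced [time_od_map()].
#'
#' @param model A [growth_model()].
#' @param times Times in minutes (>= 0).
#' @return `growth_od`: OD600 values.  `generate_growth_curve`: a list with
#'   `curve` (data.frame `time_min`, `od600`) and `map` (a `time_od_map`).
#' @export
growth_od <- function(model, times) {
  stopifnot(inherits(model, "growth_model"))
  with(model, K / (1 + ((K - od0) / od0) * exp(-r * times)))
}

#' @rdname growth_od
#' @param od OD600 values in (od0, K).
#' @export
growth_time_at_od <- function(model, od) {
  stopifnot(inherits(model, "growth_model"))
  if (any(od < model$od0 | od >= model$K)) {
    stop("OD must lie in [od0, K) to invert the growth curve")
  }
  with(model, log(((K - od0) / od0) / (K / od - 1)) / r)
}

#' @rdname growth_od
#' @export
generate_growth_curve <- function(model, times = seq(0, 400, by = 10)) {
  od <- growth_od(model, times)
  list(curve = data.frame(time_min = times, od600 = od),
       map = time_od_map(times, od))
}

#' Multiplicative lognormal noise specification
#'
#' Densitometry and qPCR errors are scale-like, so the generators perturb
#' true values by mean-one lognormal factors with a stated coefficient of
#' variation.  The same spec and seed always reproduce the same draws.
#'
#' @param cv Coefficient of variation (>= 0); 0 disables noise.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.1, seed = 1L) {
  stopifnot(is.numeric(cv), cv >= 0, is.numeric(seed))
  if (cv >= 1) warning("noise cv >= 1 distorts trajectories heavily")
  structure(list(cv = cv, seed = as.integer(seed)), class = "noise_spec")
}

# mean-one multiplicative lognormal factors
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Integrate dP/dt = ks(t) - kd(t) P with restarts at any supplied
# discontinuity times, so step profiles are handled exactly.
solve_general <- function(kd_fun, ks_fun, p0, times, breaks = numeric(0)) {
  stopifnot(times[1] >= 0)
  grid <- sort(unique(c(0, times, breaks[breaks > 0 & breaks < max(times)])))
  deriv <- function(t, y, parms) list(ks_fun(t) - kd_fun(t) * y)
  segs <- sort(unique(c(0, breaks[breaks > 0 & breaks < max(times)],
                        max(times))))
  out_t <- numeric(0); out_p <- numeric(0)
  p <- p0
  for (i in seq_len(length(segs) - 1)) {
    tt <- grid[grid >= segs[i] & grid <= segs[i + 1]]
    if (length(tt) < 2) tt <- c(segs[i], segs[i + 1])
    # evaluate ks/kd just inside the segment so step profiles take the
    # segment's own value at its left edge
    eps <- (segs[i + 1] - segs[i]) * 1e-9
    deriv_seg <- function(t, y, parms) {
      ts <- min(max(t, segs[i] + eps), segs[i + 1] - eps)
      list(ks_fun(ts) - kd_fun(ts) * y)
    }
    sol <- deSolve::ode(y = c(P = p), times = tt, func = deriv_seg,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    p <- as.numeric(sol[nrow(sol), 2])
    out_t <- c(out_t, sol[, 1]); out_p <- c(out_p, sol[, 2])
  }
  keep <- !duplicated(out_t)
  stats::approx(out_t[keep], out_p[keep], xout = times)$y
}

#' Turn a synthesis-rate specification into a function of time
#'
#' Accepts a constant, a piecewise-constant profile
#' `list(breaks = c(t1, ...), values = c(v0, v1, ...))` (value `v0` before
#' `t1`, `v1` on `[t1, t2)`, ...), or an arbitrary function of time.
#'
#' @param ks Constant, piecewise list, or `function(t)`.
#' @return A vectorized `function(t)` and, as attribute `"breaks"`, any
#'   discontinuity times.
#' @keywords internal
ks_profile <- function(ks) {
  if (is.function(ks)) {
    f <- ks
    attr(f, "breaks") <- numeric(0)
    return(f)
  }
  if (is.numeric(ks) && length(ks) == 1L) {
    f <- function(t) rep(ks, length(t))
    attr(f, "breaks") <- numeric(0)
    return(f)
  }
  if (is.list(ks) && all(c("breaks", "values") %in% names(ks))) {
    breaks <- ks$breaks; values <- ks$values
    stopifnot(length(values) == length(breaks) + 1L,
              !is.unsorted(breaks, strictly = TRUE))
    f <- function(t) values[findInterval(t, breaks) + 1L]
    attr(f, "breaks") <- breaks
    return(f)
  }
  stop("ks must be a constant, a list(breaks, values), or a function")
}

#' Generate a noisy abundance time course from a turnover model
#'
#' Forward-solves `dP/dt = ks(t) - kd(t) P` and perturbs each replicate by
#' mean-one multiplicative lognormal noise, emulating band-densitometry
#' quantification of a protein across a growth curve.  The returned series
#' is the replicate mean (the quantity a blot quantification reports), with
#' replicate SD attached; per-replicate draws are available in the
#' `"replicates"` attribute.
#'
#' @param schedule A [degradation_schedule()], or a `function(t)` returning
#'   kd(t) for non-linear schedules (e.g. a step matching measured
#'   half-lives).
#' @param ks Synthesis-rate specification: constant, piecewise list, or
#'   function of time (see [ks_profile()]).
#' @param sample_times Times (minutes) at which samples are taken.
#' @param p0 Initial relative abundance.
#' @param noise A [noise_spec()].
#' @param n_replicates Number of independent replicates.
#' @param od_map Optional [time_od_map()] to attach OD600 to the samples.
#' @param labels Optional per-point labels (e.g. `"overnight"`).
#' @return An [abundance_series()] of replicate means with an `sd` column
#'   and a `"replicates"` attribute (tidy per-replicate data.frame).
#' @export
generate_abundance_course <- function(schedule, ks, sample_times, p0 = 1,
                                      noise = noise_spec(0.1, 1L),
                                      n_replicates = 2L, od_map = NULL,
                                      labels = NULL) {
  stopifnot(inherits(noise, "noise_spec"), n_replicates >= 1L)
  kd_fun <- if (is.function(schedule)) {
    schedule
  } else {
    stopifnot(inherits(schedule, "degradation_schedule"))
    check_in_window(schedule, sample_times)
    function(t) schedule$a * t + schedule$kd0
  }
  ksf <- ks_profile(ks)
  truth <- solve_general(kd_fun, ksf, p0, sample_times,
                         breaks = attr(ksf, "breaks"))
  set.seed(noise$seed)
  mat <- vapply(seq_len(n_replicates), function(r) {
    truth * noise_factors(length(truth), noise$cv)
  }, numeric(length(truth)))
  mat <- matrix(mat, nrow = length(truth))
  reps <- data.frame(
    replicate = rep(seq_len(n_replicates), each = length(truth)),
    time_min = rep(sample_times, n_replicates),
    abundance = as.numeric(mat))
  sd_ab <- if (n_replicates >= 2) apply(mat, 1, stats::sd) else NULL
  od <- if (!is.null(od_map)) od_at_time(od_map, sample_times) else NULL
  out <- abundance_series(sample_times, rowMeans(mat),
                          od600 = od, label = labels, sd = sd_ab)
  attr(out, "replicates") <- reps
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic chase (shut-off) assay
#'
#' Pure first-order decay `2^(-t / halflife)` per replicate, perturbed by
#' multiplicative lognormal noise, emulating band intensities sampled every
#' 10 minutes after chloramphenicol addition.
#'
#' @param halflife True half-life, minutes.
#' @param times Sampling times (minutes), starting at 0; default every
#'   10 min over a 30-min chase.
#' @param noise A [noise_spec()].
#' @param n_replicates Number of replicates.
#' @param condition Condition label.
#' @return A [chase_course()].
#' @export
generate_chase_course <- function(halflife, times = seq(0, 30, by = 10),
                                  noise = noise_spec(0.1, 1L),
                                  n_replicates = 2L,
                                  condition = "condition") {
  stopifnot(halflife > 0, inherits(noise, "noise_spec"))
  truth <- 2^(-times / halflife)
  set.seed(noise$seed)
  courses <- lapply(seq_len(n_replicates), function(r) {
    chase_course(times, truth * noise_factors(length(times), noise$cv),
                 replicate = r, condition = condition)
  })
  out <- do.call(rbind, courses)
  rownames(out) <- NULL
  class(out) <- c("chase_course", "data.frame")
  out
}

#' Generate a synthetic qPCR Ct table
#'
#' For each sample, the target gene's Ct is `base_ct - log2(rel_expr)` plus
#' normal jitter; the reference gene sits at a constant Ct plus jitter.
#' Running [delta_delta_ct()] on the result recovers the generating fold
#' changes exactly at zero jitter and in expectation otherwise.
#'
#' @param true_rel_expr Named numeric vector of true relative expressions
#'   per sample (the calibrator should have value 1).
#' @param reference Reference gene name (default `"16S"`).
#' @param target Target gene name (default `"target"`).
#' @param base_ct Target Ct at relative expression 1 (cycles).
#' @param ref_ct Reference gene Ct (cycles).
#' @param sd_ct Technical jitter SD in cycles (default 0.2).
#' @param n_replicates Technical replicates per well (default 3).
#' @param od600 Optional named numeric vector of OD600 per sample.
#' @param seed Integer seed.
#' @return A [ct_table()].
#' @export
generate_ct_table <- function(true_rel_expr, reference = "16S",
                              target = "target", base_ct = 20, ref_ct = 12,
                              sd_ct = 0.2, n_replicates = 3L, od600 = NULL,
                              seed = 1L) {
  stopifnot(is.numeric(true_rel_expr), all(true_rel_expr > 0),
            !is.null(names(true_rel_expr)))
  set.seed(seed)
  rows <- list()
  for (s in names(true_rel_expr)) {
    ct_t <- base_ct - log2(true_rel_expr[[s]]) +
      stats::rnorm(n_replicates, sd = sd_ct)
    ct_r <- ref_ct + stats::rnorm(n_replicates, sd = sd_ct)
    od <- if (!is.null(od600)) od600[[s]] else NA_real_
    rows[[s]] <- data.frame(
      sample = s, gene = rep(c(target, reference), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2L),
      ct = c(ct_t, ct_r), od600 = od)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (is.null(od600)) df$od600 <- NULL
  as_ct_table(df)
}
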