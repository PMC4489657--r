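#' Global slope of an abundance time course
#'
#' Ordinary least-squares slope of relative abundance against time over the
#' included points.  The point-wise synthesis estimator uses this single
#' global slope as its estimate of dP/dt, matching the sparse sampling of
#' densitometry time courses; a per-point finite-difference derivative is
#' available in [infer_synthesis_pointwise()] behind a flag.
#'
#' @param data An [abundance_series()].
#' @param exclude_labels Labels of points to exclude (default the overnight
#'   sample, which has no meaningful abscissa in minutes).
#' @return Slope in relative-abundance units per minute.
#' @export
fit_global_slope <- function(data, exclude_labels = "overnight") {
  stopifnot(inherits(data, "abundance_series"))
  data <- exclude_by_label(data, exclude_labels)
  if (nrow(data) < 2L) stop("need at least 2 included points for a slope")
  unname(stats::coef(stats::lm(abundance ~ time_min, data = data))["time_min"])
}

#' Half-life assignment for a sampled time course
#'
#' Maps each abundance time point to the half-life assumed to hold there.
#' The default rule for a 4-point course assigns the exponential-phase
#' half-life (`halflife_t0`) to the first two points and the
#' stationary-onset half-life (`halflife_t1`) to the last two.  For other
#' lengths the first half of the points (rounded up) get `halflife_t0` and
#' the rest `halflife_t1`; an explicit numeric vector overrides the rule.
#'
#' @param data An [abundance_series()] (after any exclusion).
#' @param halflife_t0 Half-life for the early points, minutes (default 23).
#' @param halflife_t1 Half-life for the late points, minutes (default 20).
#' @param explicit Optional numeric vector of half-lives, one per point.
#' @return Numeric vector of half-lives (minutes), one per row of `data`.
#' @export
assign_halflives <- function(data, halflife_t0 = 23, halflife_t1 = 20,
                             explicit = NULL) {
  stopifnot(inherits(data, "abundance_series"))
  n <- nrow(data)
  if (!is.null(explicit)) {
    stopifnot(is.numeric(explicit), length(explicit) == n, all(explicit > 0))
    return(explicit)
  }
  stopifnot(halflife_t0 > 0, halflife_t1 > 0)
  n_early <- ceiling(n / 2)
  c(rep(halflife_t0, n_early), rep(halflife_t1, n - n_early))
}

#' Point-wise inference of the synthesis rate
#'
#' Rearranges the turnover equation to solve for a time-varying synthesis
#' rate at each measured point:
#' `ks(t_i) = dP/dt + kd(t_i) * P(t_i)`, with dP/dt taken as the single
#' global slope from [fit_global_slope()] and `kd(t_i) = ln2 / halflife_i`
#' from a [assign_halflives()] mapping.  The raw rates are then normalized
#' to the first point.  Negative raw rates (possible under measurement
#' noise) are retained with a warning, never clipped.
#'
#' @param data An [abundance_series()].
#' @param halflives Numeric vector of half-lives (minutes), one per row of
#'   `data` after exclusion; see [assign_halflives()].
#' @param slope dP/dt estimate; default computed by [fit_global_slope()]
#'   on the same data and exclusions.
#' @param exclude_labels Labels dropped before inference (default
#'   "overnight").
#' @param derivative `"global"` (single OLS slope, default) or `"finite"`
#'   (central finite differences per point).
#' @return A data.frame of class `synthesis_profile` with columns
#'   `time_min`, `od600` (if present), `ks_raw` (per minute) and `ks_norm`
#'   (first point = 1).
#' @export
infer_synthesis_pointwise <- function(data, halflives = NULL, slope = NULL,
                                      exclude_labels = "overnight",
                                      derivative = c("global", "finite")) {
  stopifnot(inherits(data, "abundance_series"))
  derivative <- match.arg(derivative)
  data <- exclude_by_label(data, exclude_labels)
  n <- nrow(data)
  if (n < 2L) stop("need at least 2 points to infer synthesis rates")
  if (is.null(halflives)) halflives <- assign_halflives(data)
  stopifnot(is.numeric(halflives), length(halflives) == n,
            all(halflives > 0))
  dPdt <- if (derivative == "global") {
    if (is.null(slope)) slope <- fit_global_slope(data, exclude_labels = NULL)
    rep(slope, n)
  } else {
    # central differences in the interior, one-sided at the ends
    t <- data$time_min; p <- data$abundance
    d <- numeric(n)
    d[1] <- (p[2] - p[1]) / (t[2] - t[1])
    d[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
    if (n > 2) {
      for (i in 2:(n - 1)) d[i] <- (p[i + 1] - p[i - 1]) / (t[i + 1] - t[i - 1])
    }
    d
  }
  ks_raw <- dPdt + rate_from_halflife(halflives) * data$abundance
  if (any(ks_raw < 0)) {
    warning(sum(ks_raw < 0),
            " inferred synthesis rate(s) are negative; retained unclipped")
  }
  if (ks_raw[1] == 0) stop("first-point synthesis rate is zero; cannot normalize")
  out <- data.frame(time_min = data$time_min)
  if (!is.null(data[["od600"]])) out$od600 <- data$od600
  out$ks_raw <- ks_raw
  out$ks_norm <- ks_raw / ks_raw[1]
  class(out) <- c("synthesis_profile", "data.frame")
  out
}

#' Convert a synthesis profile to a translation-rate profile
#'
#' Divides the inferred synthesis rate at each point by the relative mRNA
#' abundance measured for the matching sample, yielding a per-transcript
#' translation rate, then renormalizes to the first point.  mRNA samples
#' are matched to protein time points by OD600 (nearest sample within
#' `od_tol`), since both assays are sampled on OD grids.
#'
#' @param synth A `synthesis_profile` from [infer_synthesis_pointwise()];
#'   must carry an `od600` column for OD matching (or supply `mrna` with a
#'   `time_min` column matching exactly).
#' @param mrna An `expression_series` (see [delta_delta_ct()]) or any
#'   data.frame with columns `od600` and `rel_expr`.
#' @param od_tol Maximum |OD difference| for a match (default 0.1).
#' @return A data.frame of class `translation_profile` with columns
#'   `time_min`, `od600`, `mrna`, `rate_raw` and `rate_norm`
#'   (first point = 1).
#' @export
translation_rates <- function(synth, mrna, od_tol = 0.1) {
  stopifnot(inherits(synth, "synthesis_profile"),
            is.data.frame(mrna), all(c("od600", "rel_expr") %in% names(mrna)))
  if (is.null(synth[["od600"]])) {
    stop("synthesis profile lacks od600; cannot match mRNA samples by OD")
  }
  if (any(mrna$rel_expr <= 0)) stop("mRNA relative expression must be positive")
  m <- vapply(synth$od600, function(od) {
    d <- abs(mrna$od600 - od)
    i <- which.min(d)
    if (d[i] > od_tol) {
      stop(sprintf(
        "no mRNA sample within %.2g OD of protein point at OD %.2g",
        od_tol, od))
    }
    mrna$rel_expr[i]
  }, numeric(1))
  rate_raw <- synth$ks_norm / m
  out <- data.frame(time_min = synth$time_min, od600 = synth$od600,
                    mrna = m, rate_raw = rate_raw,
                    rate_norm = rate_raw / rate_raw[1])
  class(out) <- c("translation_profile", "data.frame")
  out
}
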