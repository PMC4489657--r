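#' Chase-assay time course
#'
#' A chase (translation shut-off) experiment follows the decay of a
#' protein's band intensity after chloramphenicol blocks synthesis, sampling
#' typically every 10 minutes.  One `chase_course` holds the intensities of
#' one condition across replicates.
#'
#' Non-positive intensities (background-subtraction artefacts) are dropped
#' with a warning rather than floored, since flooring biases the decay
#' slope.
#'
#' @param times Minutes after shut-off, starting at 0, strictly increasing
#'   within each replicate.
#' @param intensities Band intensities (arbitrary units), same length.
#' @param replicate Replicate identifier per observation (default: all one
#'   replicate).
#' @param condition Condition label for the course.
#' @return A data.frame of class `chase_course` with columns `condition`,
#'   `replicate`, `time_min`, `intensity`.
#' @export
chase_course <- function(times, intensities, replicate = 1L,
                         condition = "condition") {
  stopifnot(is.numeric(times), is.numeric(intensities),
            length(times) == length(intensities))
  replicate <- rep_len(replicate, length(times))
  keep <- is.finite(intensities) & intensities > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive or missing intensities dropped")
  }
  out <- data.frame(condition = condition,
                    replicate = replicate[keep],
                    time_min = times[keep],
                    intensity = intensities[keep])
  for (r in unique(out$replicate)) {
    tr <- out$time_min[out$replicate == r]
    if (is.unsorted(tr, strictly = TRUE)) {
      stop("chase times must be strictly increasing within replicate ", r)
    }
    if (length(tr) < 3L) {
      stop("replicate ", r, " has fewer than 3 usable time points")
    }
    if (min(tr) != 0) {
      stop("chase must include a t = 0 sample (replicate ", r, ")")
    }
  }
  class(out) <- c("chase_course", "data.frame")
  out
}

as_chase_course <- function(df) {
  need <- c("condition", "replicate", "time_min", "intensity")
  stopifnot(all(need %in% names(df)))
  split_by_rep <- split(df, df$replicate)
  courses <- lapply(split_by_rep, function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    chase_course(d$time_min, d$intensity, d$replicate, d$condition[1])
  })
  out <- do.call(rbind, courses)
  rownames(out) <- NULL
  class(out) <- c("chase_course", "data.frame")
  out
}

#' Normalize a chase course to its t = 0 intensity
#'
#' Each replicate is divided by its own t = 0 band intensity so that the
#' normalized value at t = 0 is exactly 1.  Idempotent.
#'
#' @param course A [chase_course()].
#' @return A `chase_course` with normalized intensities.
#' @export
normalize_chase <- function(course) {
  stopifnot(inherits(course, "chase_course"))
  out <- course
  for (r in unique(out$replicate)) {
    idx <- out$replicate == r
    i0 <- out$intensity[idx & out$time_min == 0]
    if (length(i0) != 1L || !is.finite(i0) || i0 <= 0) {
      stop("replicate ", r, " lacks a single positive t = 0 intensity")
    }
    out$intensity[idx] <- out$intensity[idx] / i0
  }
  out
}

#' Estimate a protein half-life from a chase course
#'
#' Fits ordinary least squares of `log2(intensity)` against time, pooling
#' replicates as stacked points, and reports `-1/slope` as the half-life in
#' minutes.  The estimate is censored — reported only as a lower bound equal
#' to the chase duration — when the fitted half-life exceeds the duration of
#' the chase or when a one-sided test of slope < 0 is not significant at
#' `alpha`.  On noise-free exponential data the estimator is exact.
#'
#' @param course A [chase_course()], normalized or not (scale per replicate
#'   does not affect the slope).
#' @param alpha Significance level for the one-sided decay test and the
#'   (two-sided) confidence interval; default 0.05.
#' @return An object of class `halflife_estimate`: a list with `halflife`
#'   (minutes), `ci` (two-sided interval), `censored`, `censor_bound`
#'   (chase duration, minutes), `slope` (log2 units/min), `slope_se`, `df`,
#'   and `condition`.
#' @export
estimate_halflife <- function(course, alpha = 0.05) {
  stopifnot(inherits(course, "chase_course"))
  if (nrow(course) < 3L) stop("need at least 3 chase points")
  duration <- max(course$time_min)
  fit <- stats::lm(log2(intensity) ~ time_min, data = course)
  slope <- unname(stats::coef(fit)["time_min"])
  sm <- suppressWarnings(summary(fit))  # noise-free data: perfect-fit warning
  slope_se <- sm$coefficients["time_min", "Std. Error"]
  df <- fit$df.residual
  # one-sided p-value for H1: slope < 0; a perfectly noise-free fit has
  # zero residual SE, treat it as decisive
  if (!is.finite(slope_se) || slope_se == 0) {
    p_one <- if (slope < 0) 0 else 1
    ci_slope <- c(slope, slope)
  } else {
    p_one <- stats::pt(slope / slope_se, df = df, lower.tail = TRUE)
    tcrit <- stats::qt(1 - alpha / 2, df = df)
    ci_slope <- slope + c(-1, 1) * tcrit * slope_se
  }
  halflife <- if (slope < 0) -1 / slope else Inf
  censored <- !is.finite(halflife) || halflife > duration || p_one > alpha
  # slope CI maps to a half-life CI by -1/slope (monotone on slope < 0)
  ci <- if (censored) {
    c(duration, Inf)
  } else {
    lo <- if (ci_slope[2] < 0) -1 / ci_slope[1] else NA_real_
    hi <- if (ci_slope[2] < 0) -1 / ci_slope[2] else Inf
    c(lo, hi)
  }
  structure(list(
    halflife = if (censored) duration else halflife,
    ci = ci,
    censored = censored,
    censor_bound = duration,
    slope = slope, slope_se = slope_se, df = df,
    condition = course$condition[1],
    alpha = alpha
  ), class = "halflife_estimate")
}

#' @export
print.halflife_estimate <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("half-life (%s): > %g min (censored at chase duration)\n",
                x$condition, x$censor_bound))
  } else {
    cat(sprintf("half-life (%s): %.3g min  [%.3g, %.3g] %d%% CI\n",
                x$condition, x$halflife, x$ci[1], x$ci[2],
                round(100 * (1 - x$alpha))))
  }
  invisible(x)
}

#' Compare two half-life estimates
#'
#' Reports the point difference `a - b` in minutes with an interval
#' propagated from the two independent slope fits (delta method on
#' -1/slope).  If either estimate is censored only a bound can be stated.
#'
#' @param est_a,est_b [estimate_halflife()] results.
#' @return A list with `difference` (minutes), `ci`, and `bound_only`.
#' @export
compare_halflives <- function(est_a, est_b) {
  stopifnot(inherits(est_a, "halflife_estimate"),
            inherits(est_b, "halflife_estimate"))
  if (est_a$censored || est_b$censored) {
    unc <- if (est_a$censored) est_b else est_a
    cen <- if (est_a$censored) est_a else est_b
    sign <- if (est_a$censored) 1 else -1
    return(list(
      difference = NA_real_, ci = c(NA_real_, NA_real_), bound_only = TRUE,
      bound = sign * (cen$censor_bound - unc$halflife)))
  }
  diff <- est_a$halflife - est_b$halflife
  # delta method: var(-1/s) = se^2 / s^4
  se <- sqrt(est_a$slope_se^2 / est_a$slope^4 +
             est_b$slope_se^2 / est_b$slope^4)
  z <- stats::qnorm(1 - est_a$alpha / 2)
  list(difference = diff, ci = diff + c(-1, 1) * z * se, bound_only = FALSE)
}
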