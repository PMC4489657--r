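#' Observed relative-abundance time course
#'
#' Band-densitometry quantifications of a protein across a growth curve:
#' one row per sampled time point, with abundance relative to the first
#' (exponential-phase) sample.  The optional `label` column marks points for
#' exclusion masks (e.g. the overnight sample, which has no well-defined
#' position on the minutes axis).
#'
#' @param time_min Sample times in minutes, strictly increasing.
#' @param abundance Relative abundances, positive.
#' @param od600 Optional OD600 at each sample.
#' @param label Optional point labels (character).
#' @param sd Optional replicate standard deviation per point.
#' @return A data.frame of class `abundance_series`.
#' @export
abundance_series <- function(time_min, abundance, od600 = NULL,
                             label = NULL, sd = NULL) {
  stopifnot(is.numeric(time_min), is.numeric(abundance),
            length(time_min) == length(abundance))
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("abundance series times must be strictly increasing")
  }
  if (any(!is.finite(abundance)) || any(abundance <= 0)) {
    stop("abundances must be positive and finite")
  }
  out <- data.frame(time_min = time_min, abundance = abundance)
  if (!is.null(od600)) out$od600 <- od600
  out$label <- if (is.null(label)) "" else as.character(label)
  if (!is.null(sd)) out$sd <- sd
  class(out) <- c("abundance_series", "data.frame")
  out
}

as_abundance_series <- function(df) {
  stopifnot(all(c("time_min", "abundance") %in% names(df)))
  df <- df[order(df$time_min), , drop = FALSE]
  abundance_series(df$time_min, df$abundance,
                   od600 = df[["od600"]], label = df[["label"]],
                   sd = df[["sd"]])
}

exclude_by_label <- function(series, exclude_labels) {
  if (length(exclude_labels) == 0) return(series)
  keep <- !(series$label %in% exclude_labels)
  out <- series[keep, , drop = FALSE]
  class(out) <- class(series)
  out
}
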