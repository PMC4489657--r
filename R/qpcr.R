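#' Build a qPCR Ct table
#'
#' One row per well: sample label, gene, replicate and threshold cycle.
#' The reference (endogenous control, e.g. 16S rRNA) must be measured in
#' every sample.  Wells failing dissociation-curve QC can be flagged via
#' `qc_pass` and are excluded with a message.
#'
#' @param sample Sample labels (character), e.g. OD600 values as strings.
#' @param gene Gene per well.
#' @param ct Threshold cycle per well; finite, positive.
#' @param replicate Technical replicate index (default 1).
#' @param od600 Optional numeric OD600 metadata per well.
#' @param qc_pass Optional logical; wells with `FALSE` are dropped.
#' @return A data.frame of class `ct_table`.
#' @export
ct_table <- function(sample, gene, ct, replicate = 1L, od600 = NULL,
                     qc_pass = NULL) {
  n <- length(ct)
  stopifnot(is.numeric(ct), length(sample) %in% c(1L, n),
            length(gene) %in% c(1L, n))
  out <- data.frame(sample = as.character(rep_len(sample, n)),
                    gene = as.character(rep_len(gene, n)),
                    replicate = rep_len(replicate, n),
                    ct = ct)
  if (!is.null(od600)) out$od600 <- rep_len(od600, n)
  if (!is.null(qc_pass)) {
    qc_pass <- rep_len(as.logical(qc_pass), n)
    if (any(!qc_pass)) {
      message(sum(!qc_pass), " well(s) failing QC excluded")
    }
    out <- out[qc_pass, , drop = FALSE]
  }
  if (any(!is.finite(out$ct)) || any(out$ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  class(out) <- c("ct_table", "data.frame")
  out
}

as_ct_table <- function(df) {
  need <- c("sample", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(df)))
  ct_table(df$sample, df$gene, df$ct, df$replicate,
           od600 = df[["od600"]], qc_pass = df[["qc_pass"]])
}

#' Relative expression by the comparative Ct method
#'
#' Classical delta-delta-Ct quantification: technical replicate Cts are
#' averaged per (sample, gene) on the Ct scale; the target is normalized to
#' the endogenous reference within each sample (dCt = Ct_target - Ct_ref);
#' each sample is then referred to the calibrator sample
#' (ddCt = dCt_sample - dCt_calibrator) and expressed as a fold change
#' `efficiency^(-ddCt)` with perfect-doubling efficiency 2.0 by default.
#'
#' @param table A [ct_table()].
#' @param target Target gene name.
#' @param reference Endogenous control gene (default `"16S"`).
#' @param calibrator Sample to which fold changes are referred; its
#'   relative expression is exactly 1.
#' @param efficiency Amplification efficiency (fold per cycle), default 2.
#' @return A data.frame of class `expression_series` with columns `sample`,
#'   `od600` (if available), `rel_expr` and `sd` (replicate spread on the
#'   linear scale; `NA` for single replicates).
#' @export
delta_delta_ct <- function(table, target, reference = "16S", calibrator,
                           efficiency = 2) {
  stopifnot(inherits(table, "ct_table"), efficiency > 1)
  samples <- unique(table$sample)
  if (!target %in% table$gene) stop("target gene not in table: ", target)
  if (!reference %in% table$gene) {
    stop("reference gene not in table: ", reference)
  }
  if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
  missing_ref <- samples[!vapply(samples, function(s)
    any(table$sample == s & table$gene == reference), logical(1))]
  if (length(missing_ref)) {
    stop("reference gene missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  mean_ct <- function(s, g) {
    v <- table$ct[table$sample == s & table$gene == g]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  sd_ct <- function(s, g) {
    v <- table$ct[table$sample == s & table$gene == g]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }
  dct <- vapply(samples, function(s)
    mean_ct(s, target) - mean_ct(s, reference), numeric(1))
  if (any(is.na(dct))) {
    stop("target gene missing in sample(s): ",
         paste(samples[is.na(dct)], collapse = ", "))
  }
  ddct <- dct - dct[samples == calibrator]
  rel <- efficiency^(-ddct)
  # propagate technical replicate SD of the target Ct onto the linear scale
  sd_lin <- vapply(samples, function(s) {
    s_ct <- sd_ct(s, target)
    if (is.na(s_ct)) NA_real_
    else rel[samples == s] * abs(log(efficiency)) * s_ct
  }, numeric(1))
  out <- data.frame(sample = samples, rel_expr = unname(rel),
                    sd = unname(sd_lin))
  if (!is.null(table[["od600"]])) {
    od <- vapply(samples, function(s)
      table$od600[table$sample == s][1], numeric(1))
    out <- data.frame(sample = samples, od600 = unname(od),
                      rel_expr = unname(rel), sd = unname(sd_lin))
  }
  rownames(out) <- NULL
  class(out) <- c("expression_series", "data.frame")
  out
}

#' Order an expression series by OD and summarize biological replicates
#'
#' Sorts samples by their OD600 metadata and, where several biological
#' replicates share an OD, reports their mean and standard deviation.
#' Single replicates report `NA` (not 0) as their SD.
#'
#' @param series An `expression_series` (or a row-bound set of them across
#'   biological replicates) carrying an `od600` column.
#' @param od_order Optional explicit OD ordering; default ascending.
#' @return A data.frame with columns `od600`, `rel_expr` (mean) and `sd`.
#' @export
summarize_series <- function(series, od_order = NULL) {
  stopifnot(is.data.frame(series),
            all(c("od600", "rel_expr") %in% names(series)))
  if (anyNA(series$od600)) stop("all samples need OD600 metadata")
  has_rep <- "replicate" %in% names(series)
  if (!has_rep && anyDuplicated(series$od600)) {
    stop("duplicate OD600 labels without replicate tags")
  }
  ods <- if (is.null(od_order)) sort(unique(series$od600)) else od_order
  out <- do.call(rbind, lapply(ods, function(od) {
    v <- series$rel_expr[series$od600 == od]
    data.frame(od600 = od, rel_expr = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
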