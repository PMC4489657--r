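#' Read a tidy CSV table against a column schema
#'
#' Thin wrapper over [utils::read.csv()] that validates the header and cell
#' types before any computation touches the data, reporting offending
#' columns and row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping required column names to
#'   `"numeric"` or `"character"`.  Extra columns are kept untouched.
#' @return A data.frame with validated, typed columns.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time_min = 0:2, abundance = c(1, .8, .6)),
#'           tf, row.names = FALSE)
#' read_table(tf, c(time_min = "numeric", abundance = "numeric"))
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      v <- df[[col]]
      if (!is.numeric(v)) {
        coerced <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(coerced) & !is.na(v) & v != "")
        if (length(bad)) {
          stop(sprintf("non-numeric value in column '%s' of %s (row %d: '%s')",
                       col, basename(path), bad[1], v[bad[1]]))
        }
        df[[col]] <- coerced
      }
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' @rdname read_table
#' @param df Data frame to write.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the input tables, analysis options and output location of a full
#' turnover analysis.  All referenced paths are checked at construction.
#'
#' @param abundance Path to the abundance CSV (`time_min`, `abundance`,
#'   optional `od600`, `label`).
#' @param chase Path to the chase CSV (`condition`, `replicate`,
#'   `time_min`, `intensity`).
#' @param qpcr Optional path to the Ct CSV (`sample`, `gene`, `replicate`,
#'   `ct`, optional `od600`); `NULL` skips the translation stage.
#' @param output_dir Directory for per-stage outputs and `summary.json`.
#' @param t0_condition,t1_condition Chase condition labels for the
#'   exponential-phase and stationary-onset half-life measurements.
#' @param t1 Time (minutes) of the second half-life anchor; default 160.
#' @param target,reference,calibrator qPCR genes and calibrator sample.
#' @param exclude_labels Abundance labels excluded from fits (default
#'   `"overnight"`).
#' @param objective Fit residual type, `"relative"` or `"log"`.
#' @param alpha Significance level for half-life censoring.
#' @param seed Integer seed (multi-start jitter in the fit stage).
#' @param verbose Emit progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance, chase, qpcr = NULL, output_dir,
                            t0_condition = "exponential",
                            t1_condition = "stationary_onset",
                            t1 = 160, target = "dnaA", reference = "16S",
                            calibrator = NULL,
                            exclude_labels = "overnight",
                            objective = "relative", alpha = 0.05,
                            seed = 1L, verbose = FALSE) {
  for (p in c(abundance, chase, qpcr)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  objective <- match.arg(objective, c("relative", "log"))
  structure(list(abundance = abundance, chase = chase, qpcr = qpcr,
                 output_dir = output_dir,
                 t0_condition = t0_condition, t1_condition = t1_condition,
                 t1 = t1, target = target, reference = reference,
                 calibrator = calibrator,
                 exclude_labels = exclude_labels, objective = objective,
                 alpha = alpha, seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

#' Run the full turnover analysis pipeline
#'
#' Executes, in order: half-life estimation from the chase table; fitting
#' of the degradation acceleration to the abundance course (with kd(0)
#' anchored at the measured exponential-phase half-life); point-wise
#' synthesis-rate inference (half-lives assigned from the two chase
#' estimates); and, when a Ct table is supplied, comparative-Ct mRNA
#' quantification and translation-rate estimation.  Per-stage CSVs and a
#' `summary.json` are written to `output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also serialized as JSON): half-life
#'   estimates, fitted `ks` and `a`, the half-life at `t1` implied by the
#'   fit, the point-wise synthesis fold change, and the terminal
#'   translation fraction (when mRNA data are present).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  # -- stage 1: half-lives from chase assays -------------------------------
  say("stage halflife: estimating half-lives from chase table")
  chase_df <- read_table(config$chase, c(condition = "character",
                                         replicate = "character",
                                         time_min = "numeric",
                                         intensity = "numeric"))
  conditions <- unique(chase_df$condition)
  estimates <- lapply(conditions, function(cond) {
    crs <- as_chase_course(chase_df[chase_df$condition == cond, ])
    estimate_halflife(normalize_chase(crs), alpha = config$alpha)
  })
  names(estimates) <- conditions
  hl_table <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(condition = e$condition, halflife_min = e$halflife,
               ci_lo = e$ci[1], ci_hi = e$ci[2], censored = e$censored,
               censor_bound_min = e$censor_bound)
  }))
  write_table(hl_table, file.path(config$output_dir, "halflives.csv"))
  for (cond in c(config$t0_condition, config$t1_condition)) {
    if (!cond %in% conditions) {
      stop("stage halflife: chase table has no condition '", cond, "'")
    }
    if (estimates[[cond]]$censored) {
      stop("stage halflife: condition '", cond,
           "' is censored; cannot anchor the degradation schedule")
    }
  }
  hl0 <- estimates[[config$t0_condition]]$halflife
  hl1 <- estimates[[config$t1_condition]]$halflife

  # -- stage 2: degradation-acceleration fit -------------------------------
  say("stage fit: fitting ks and a to the abundance course")
  ab_df <- read_table(config$abundance, c(time_min = "numeric",
                                          abundance = "numeric"))
  series <- as_abundance_series(ab_df)
  fit <- fit_degradation_acceleration(
    series, halflife_t0 = hl0, exclude_labels = config$exclude_labels,
    objective = config$objective, seed = config$seed)
  fit_report <- data.frame(ks = fit$ks, a = fit$a, kd0 = fit$kd0,
                           objective = fit$objective,
                           halflife_t1 = fit$halflife_at(
                             min(config$t1, fit$window[2])))
  write_table(fit_report, file.path(config$output_dir, "fit.csv"))

  # -- stage 3: point-wise synthesis inference -----------------------------
  say("stage infer-synthesis: point-wise ks(t)")
  included <- exclude_by_label(series, config$exclude_labels)
  halflives <- assign_halflives(included, halflife_t0 = hl0,
                                halflife_t1 = hl1)
  synth <- infer_synthesis_pointwise(series, halflives = halflives,
                                     exclude_labels = config$exclude_labels)
  write_table(as.data.frame(synth),
              file.path(config$output_dir, "synthesis.csv"))
  synth_fold <- synth$ks_norm[1] / synth$ks_norm[nrow(synth)]

  # -- stage 4: qPCR and translation rates ---------------------------------
  translation_terminal <- NULL
  if (!is.null(config$qpcr)) {
    say("stage qpcr: comparative-Ct quantification and translation rates")
    ct_df <- read_table(config$qpcr, c(sample = "character",
                                       gene = "character",
                                       replicate = "character",
                                       ct = "numeric"))
    tab <- as_ct_table(ct_df)
    calibrator <- config$calibrator
    if (is.null(calibrator)) {
      stop("stage qpcr: a calibrator sample must be specified")
    }
    expr <- delta_delta_ct(tab, target = config$target,
                           reference = config$reference,
                           calibrator = calibrator)
    write_table(as.data.frame(expr),
                file.path(config$output_dir, "expression.csv"))
    trans <- translation_rates(synth, expr)
    write_table(as.data.frame(trans),
                file.path(config$output_dir, "translation.csv"))
    translation_terminal <- trans$rate_norm[nrow(trans)]
  } else {
    say("stage qpcr: no Ct table supplied; translation profile skipped")
  }

  summary <- list(
    halflife = lapply(estimates, function(e) list(
      condition = e$condition,
      halflife_min = round(e$halflife, 6),
      censored = e$censored,
      censor_bound_min = e$censor_bound)),
    fit = list(ks = round(fit$ks, 8), a = round(fit$a, 10),
               kd0 = round(fit$kd0, 8),
               objective = round(fit$objective, 10),
               halflife_at_t1_min = round(fit_report$halflife_t1, 6)),
    synthesis = list(fold_decrease = round(synth_fold, 6),
                     terminal_fraction = round(1 / synth_fold, 8)),
    translation = if (is.null(translation_terminal)) "skipped" else
      list(terminal_fraction = round(translation_terminal, 8)),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", config$output_dir)
  invisible(summary)
}
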