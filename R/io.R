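# CSV exchange of trial records and CSV/JSON export of cohort summaries.
# CSV schema (header required, UTF-8, comma-separated):
#   study_label, registry_id, comparison, endpoint_label, endpoint_rank,
#   exp_total, exp_events, ctrl_total, ctrl_events, reported_p,
#   allocation_ratio
# Counts are integers; reported_p may be empty.

trial_schema_cols <- c("study_label", "registry_id", "comparison",
                       "endpoint_label", "endpoint_rank", "exp_total",
                       "exp_events", "ctrl_total", "ctrl_events",
                       "reported_p", "allocation_ratio")

#' Read trial records from CSV
#'
#' Reads a cohort of trials from the documented CSV schema and validates
#' every row (count invariants, endpoint rank, 1:1 allocation). Errors name
#' the offending row.
#'
#' @param path Path to a CSV file.
#' @return A validated trial-record data frame.
#' @seealso [write_trials()] for the inverse; a copy of the built-in cohort
#'   ships at `system.file("extdata", "table1.csv", package = "rctfragility")`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(trial_schema_cols, names(trials))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trials <- trials[, trial_schema_cols]
  for (col in c("exp_total", "exp_events", "ctrl_total", "ctrl_events")) {
    parsed <- suppressWarnings(as.integer(trials[[col]]))
    bad <- is.na(parsed) | parsed != suppressWarnings(as.numeric(trials[[col]]))
    if (any(bad)) {
      stop(path, " line ", which(bad)[1L] + 1L, ": column '", col,
           "' must be an integer count (got '", trials[[col]][which(bad)[1L]],
           "')", call. = FALSE)
    }
    trials[[col]] <- parsed
  }
  trials$reported_p <- suppressWarnings(as.numeric(trials$reported_p))
  tryCatch(validate_trials(trials), error = function(e) {
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
  trials
}

#' Write trial records to CSV
#'
#' Writes the documented schema columns; [read_trials()] on the result
#' reproduces the records exactly (round-trip identity).
#'
#' @param trials A trial-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, trial_schema_cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Write a cohort fragility summary to CSV or JSON
#'
#' `"csv"` writes the per-trial table (trial record plus `n`, `fi`,
#' `fq_percent`, `baseline_p`, `converged`). `"json"` writes a document with
#' the cohort aggregates and the per-trial rows.
#'
#' @param summary A [fragility_summary()] object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, format = c("csv", "json")) {
  stopifnot(inherits(summary, "fragility_summary"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(summary$results, path, row.names = FALSE, na = "")
  } else {
    doc <- list(
      n_trials = summary$n_trials,
      alpha = summary$alpha,
      convention = summary$convention,
      median_fi = summary$median_fi,
      fi_iqr = summary$fi_iqr,
      median_n = summary$median_n,
      n_iqr = summary$n_iqr,
      n_fi_zero_primary = summary$n_fi_zero_primary,
      n_primary = summary$n_primary,
      per_trial = summary$results
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
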