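# Cohort stage: fragility analysis over a set of trials, with the built-in
# cohort of six phase-3 HCC trials and the median/IQR aggregation used to
# summarize it.

#' Built-in cohort: six phase-3 HCC trials with 1:1 randomization
#'
#' The six hepatocellular-carcinoma phase-3 randomized controlled trials
#' whose published 2x2 outcome counts form the package's reference cohort:
#' SILIUS (sorafenib plus hepatic arterial infusion chemotherapy), adjuvant
#' TACE, CIK-cell immunotherapy, SHARP (sorafenib vs placebo), hepatectomy
#' plus TACE, and sirolimus after liver transplantation. Five report a
#' primary endpoint, one (the transplantation trial) a secondary
#' overall-survival endpoint. `reported_p` is the significance level each
#' publication reported (typically from a stratified log-rank test, not a
#' Fisher test) and is carried as metadata only, never used in computation.
#'
#' @param reported If `TRUE`, append `reported_fi` and `reported_fq_percent`
#'   columns with the fragility values as originally published, for
#'   side-by-side reproduction checks.
#'
#' @return A data frame of trial records, one row per trial, in the package's
#'   trial-record schema (see [read_trials()]).
#'
#' @examples
#' hcc_trials()
#' @export
hcc_trials <- function(reported = FALSE) {
  trials <- data.frame(
    study_label = c("Kudo 2018 (SILIUS)", "Wang 2018", "Lee 2015",
                    "Llovet 2008 (SHARP)", "Wei 2018", "Geissler 2016"),
    registry_id = c("NCT01214343", "NCT01966133", "NCT00699816",
                    "NCT00105443", "NCT02788526", "NCT0035586"),
    comparison = c("Sorafenib plus HAIC vs. sorafenib",
                   "Adjuvant TACE vs. no adjuvant TACE",
                   "CIK cell agent vs. no CIK cell agent",
                   "Sorafenib vs. placebo",
                   "Hepatectomy plus TACE vs. hepatectomy",
                   "Liver transplantation with sirolimus vs. liver transplantation"),
    endpoint_label = c("Overall response", "Recurrence-free survival",
                       "Recurrence-free survival", "Overall survival",
                       "Disease-free survival", "Overall survival"),
    endpoint_rank = c("primary", "primary", "primary", "primary", "primary",
                      "secondary"),
    exp_total = c(102L, 140L, 114L, 299L, 116L, 252L),
    exp_events = c(37L, 46L, 69L, 44L, 83L, 242L),
    ctrl_total = c(103L, 140L, 112L, 303L, 118L, 256L),
    ctrl_events = c(18L, 82L, 59L, 33L, 85L, 234L),
    reported_p = c(0.003, 0.011, 0.01, 0.00583, 0.02, NA),
    allocation_ratio = "1:1",
    stringsAsFactors = FALSE
  )
  if (reported) {
    trials$reported_fi <- c(7L, 19L, 0L, 0L, 0L, 1L)
    trials$reported_fq_percent <- c(3.41, 6.79, 0, 0, 0, 0.20)
  }
  trials
}

#' Quantile with (n+1)-position linear interpolation
#'
#' The order statistic at position `(n + 1) * q`, linearly interpolated
#' between neighbouring sorted values and clamped to the extremes when the
#' position falls outside `[1, n]`. This is `stats::quantile(type = 6)`, the
#' convention (common in clinical biostatistics software) that reproduces the
#' reference cohort's published quartiles; the default type 7 does not.
#'
#' @param x Non-empty numeric vector.
#' @param q Probabilities in \eqn{[0, 1]}.
#' @return Numeric vector of quantiles, one per element of `q`.
#'
#' @examples
#' quantile_n1(c(0, 0, 0, 1, 7, 19), c(0.25, 0.5, 0.75))  # 0, 0.5, 10
#' @export
quantile_n1 <- function(x, q) {
  if (length(x) == 0L) stop("cannot take quantiles of an empty vector",
                            call. = FALSE)
  stopifnot(all(q >= 0 & q <= 1))
  unname(stats::quantile(x, probs = q, type = 6, names = FALSE))
}

validate_trials <- function(trials) {
  required <- c("study_label", "registry_id", "comparison", "endpoint_label",
                "endpoint_rank", "exp_total", "exp_events", "ctrl_total",
                "ctrl_events", "reported_p", "allocation_ratio")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("trial table has no rows", call. = FALSE)
  bad_rank <- !trials$endpoint_rank %in% c("primary", "secondary")
  if (any(bad_rank)) {
    stop("row ", which(bad_rank)[1L],
         ": endpoint_rank must be 'primary' or 'secondary'", call. = FALSE)
  }
  non11 <- trials$allocation_ratio != "1:1"
  if (any(non11)) {
    stop("row ", which(non11)[1L], " (", trials$study_label[which(non11)[1L]],
         "): fragility analysis is defined only for 1:1 allocation; ",
         "exclude non-1:1 trials before summarizing", call. = FALSE)
  }
  for (i in seq_len(nrow(trials))) {
    tryCatch(
      contingency_table(trials$exp_events[i], trials$exp_total[i],
                        trials$ctrl_events[i], trials$ctrl_total[i]),
      error = function(e) stop("row ", i, " (", trials$study_label[i], "): ",
                               conditionMessage(e), call. = FALSE))
  }
  invisible(trials)
}

#' Fragility analysis of a trial cohort
#'
#' Computes the fragility index and quotient for every trial in a cohort and
#' aggregates them: median and IQR of the FI, median and IQR of the total
#' sample size (both via [quantile_n1()]), and the count of primary-endpoint
#' trials whose FI is 0 — i.e. whose result is not even significant under the
#' baseline Fisher test, typically because the published significance came
#' from a time-to-event test.
#'
#' @param trials A trial-record data frame, e.g. [hcc_trials()] or
#'   [read_trials()]. Every row must be a 1:1 trial.
#' @param alpha,convention Passed to [fragility()].
#'
#' @return An object of class `"fragility_summary"`: a list with `results`
#'   (the trial table plus columns `n`, `fi`, `fq_percent` rounded half-up to
#'   2 dp, `baseline_p`, `converged`), `fits` (the full [fragility()] objects),
#'   and aggregates `median_fi`, `fi_iqr`, `median_n`, `n_iqr`,
#'   `n_fi_zero_primary`, `n_primary`, `n_trials`, `alpha`, `convention`.
#'
#' @examples
#' fragility_summary(hcc_trials())
#' @export
fragility_summary <- function(trials, alpha = 0.05,
                              convention = c("fewest_events", "experimental",
                                             "control")) {
  convention <- match.arg(convention)
  validate_trials(trials)
  fits <- lapply(seq_len(nrow(trials)), function(i) {
    tab <- contingency_table(trials$exp_events[i], trials$exp_total[i],
                             trials$ctrl_events[i], trials$ctrl_total[i])
    fragility(tab, alpha = alpha, convention = convention)
  })
  names(fits) <- trials$study_label
  results <- trials
  results$n <- vapply(fits, `[[`, integer(1), "n")
  results$fi <- vapply(fits, `[[`, integer(1), "fi")
  results$fq_percent <- round_half_up(vapply(fits, `[[`, numeric(1),
                                             "fq_percent"))
  results$baseline_p <- vapply(fits, `[[`, numeric(1), "baseline_p")
  results$converged <- vapply(fits, `[[`, logical(1), "converged")

  primary <- results$endpoint_rank == "primary"
  structure(list(
    results = results,
    fits = fits,
    median_fi = quantile_n1(results$fi, 0.5),
    fi_iqr = quantile_n1(results$fi, c(0.25, 0.75)),
    median_n = quantile_n1(results$n, 0.5),
    n_iqr = quantile_n1(results$n, c(0.25, 0.75)),
    n_fi_zero_primary = sum(primary & results$fi == 0L),
    n_primary = sum(primary),
    n_trials = nrow(results),
    alpha = alpha,
    convention = convention
  ), class = "fragility_summary")
}

#' @export
print.fragility_summary <- function(x, ...) {
  cat(sprintf("Fragility analysis of %d trials (alpha = %g, %s convention)\n\n",
              x$n_trials, x$alpha, x$convention))
  shown <- x$results[, c("study_label", "endpoint_rank", "n", "fi",
                         "fq_percent", "baseline_p")]
  shown$baseline_p <- signif(shown$baseline_p, 3)
  print(shown, row.names = FALSE)
  cat(sprintf("\nMedian FI %g (IQR %g-%g); median N %g (IQR %g-%g)\n",
              x$median_fi, x$fi_iqr[1], x$fi_iqr[2],
              x$median_n, x$n_iqr[1], x$n_iqr[2]))
  cat(sprintf("%d of %d primary-endpoint trials have FI = 0 (baseline Fisher p >= alpha)\n",
              x$n_fi_zero_primary, x$n_primary))
  invisible(x)
}
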