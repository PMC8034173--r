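# Fragility index: the minimum number of patients in one arm whose outcome
# would need to flip from non-event to event for a significant Fisher result
# to lose significance. Fragility quotient: FI scaled by total sample size.

#' Select the arm to which events are added
#'
#' Under the default `"fewest_events"` convention the arm with the smaller
#' event count receives the added events (ties go to the experimental arm);
#' this is the convention of the widely used web fragility calculators, and
#' the only one that can nullify significance regardless of which arm carries
#' the excess events. `"experimental"` and `"control"` force that arm
#' unconditionally.
#'
#' @param table A [contingency_table()].
#' @param convention One of `"fewest_events"`, `"experimental"`, `"control"`.
#'
#' @return `"experimental"` or `"control"`.
#' @export
select_target_arm <- function(table,
                              convention = c("fewest_events", "experimental",
                                             "control")) {
  stopifnot(inherits(table, "fragility_table"))
  convention <- match.arg(convention)
  switch(convention,
         experimental = "experimental",
         control = "control",
         fewest_events =
           if (table$experimental$events <= table$control$events)
             "experimental" else "control")
}

#' Convert one non-event to an event in one arm
#'
#' Increments the arm's event count by one; arm totals (and hence the grand
#' total) are unchanged — a patient's status flips, nobody enters or leaves
#' the trial.
#'
#' @param table A [contingency_table()].
#' @param arm `"experimental"` or `"control"`.
#'
#' @return A new `fragility_table`. Errors with condition class
#'   `"fragility_saturation"` if the arm has no non-events left.
#' @export
add_event <- function(table, arm = c("experimental", "control")) {
  stopifnot(inherits(table, "fragility_table"))
  arm <- match.arg(arm)
  a <- table[[arm]]
  if (a$events >= a$total) {
    stop(structure(
      class = c("fragility_saturation", "error", "condition"),
      list(message = sprintf("%s arm is saturated (%d events of %d); no non-event to convert",
                             arm, a$events, a$total),
           call = sys.call(-1))))
  }
  table[[arm]]$events <- a$events + 1L
  table
}

#' Fragility index of a 2x2 trial result
#'
#' Runs the iterative event-addition algorithm: if the baseline two-sided
#' Fisher p-value is already `>= alpha` the result is not significant by this
#' test and FI = 0 (trials whose reported significance came from a different
#' test, e.g. a stratified log-rank, commonly land here). Otherwise events
#' are added one at a time to the convention-selected arm — re-selected after
#' every step under `"fewest_events"` — until the p-value first reaches
#' `alpha`; the number of additions is the fragility index. Significance is
#' deemed lost at `p >= alpha` (exact equality counts as nullified).
#'
#' If the target arm runs out of non-events before the p-value crosses
#' `alpha`, the iteration stops with `converged = FALSE` and a warning; the
#' step count so far is reported.
#'
#' @param table A [contingency_table()].
#' @param alpha Significance threshold, in (0, 1). Default 0.05.
#' @param convention Arm-selection convention, see [select_target_arm()].
#'
#' @return An object of class `"fragility"`: a list with
#' \describe{
#'   \item{fi}{the fragility index (non-negative integer)}
#'   \item{fq_percent}{unrounded fragility quotient, `100 * fi / N`}
#'   \item{baseline_p}{two-sided Fisher p of the input table}
#'   \item{final_p}{p after the last addition (equals `baseline_p` when FI = 0)}
#'   \item{modified_arm}{`"experimental"`, `"control"`, or `"none"`}
#'   \item{trace}{data frame with one row per addition: `step`, `arm`,
#'     `exp_events`, `ctrl_events`, `p`}
#'   \item{converged}{`FALSE` only when the target arm saturated first}
#'   \item{n}{total sample size}
#'   \item{alpha}{`alpha` as supplied}
#'   \item{convention}{convention as matched}
#' }
#'
#' @examples
#' fragility(contingency_table(46, 140, 82, 140))  # FI = 19
#' fragility(contingency_table(69, 114, 59, 112))  # FI = 0, baseline p > 0.05
#' @export
fragility <- function(table, alpha = 0.05,
                      convention = c("fewest_events", "experimental",
                                     "control")) {
  stopifnot(inherits(table, "fragility_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  convention <- match.arg(convention)
  n <- grand_total(table)
  baseline_p <- fisher_exact(table)$p_two_sided

  trace <- data.frame(step = integer(), arm = character(),
                      exp_events = integer(), ctrl_events = integer(),
                      p = numeric(), stringsAsFactors = FALSE)
  converged <- TRUE
  modified_arm <- "none"
  p <- baseline_p
  cur <- table
  if (baseline_p < alpha) {
    step <- 0L
    repeat {
      arm <- select_target_arm(cur, convention)
      cur <- tryCatch(add_event(cur, arm), fragility_saturation = function(e) {
        warning(conditionMessage(e), "; fragility iteration did not converge",
                call. = FALSE)
        NULL
      })
      if (is.null(cur)) {
        converged <- FALSE
        break
      }
      step <- step + 1L
      if (step == 1L) modified_arm <- arm
      p <- fisher_exact(cur)$p_two_sided
      trace[step, c("step", "arm")] <- list(step, arm)
      trace[step, c("exp_events", "ctrl_events", "p")] <-
        list(cur$experimental$events, cur$control$events, p)
      if (p >= alpha) break
    }
  }
  fi <- nrow(trace)
  structure(list(fi = fi,
                 fq_percent = fragility_quotient(fi, n),
                 baseline_p = baseline_p,
                 final_p = p,
                 modified_arm = modified_arm,
                 trace = trace,
                 converged = converged,
                 n = n,
                 alpha = alpha,
                 convention = convention),
            class = "fragility")
}

#' Fragility quotient
#'
#' The fragility index divided by the trial's total sample size, expressed as
#' a percentage. Contextualizes the FI against trial size: an FI of 5 means
#' something different in a 100-patient trial than in a 5000-patient one.
#'
#' @param fi Non-negative integer fragility index.
#' @param total_n Total sample size across both arms (`>= 2`).
#'
#' @return `100 * fi / total_n`, unrounded. Report layers round half-up to
#'   two decimals via [round_half_up()].
#'
#' @examples
#' fragility_quotient(19, 280)  # 6.785714..., prints as 6.79%
#' @export
fragility_quotient <- function(fi, total_n) {
  stopifnot(length(fi) == length(total_n) || length(fi) == 1L ||
              length(total_n) == 1L)
  if (any(fi < 0) || any(fi != floor(fi))) {
    stop("fi must be a non-negative integer", call. = FALSE)
  }
  if (any(total_n < 2)) stop("total_n must be at least 2", call. = FALSE)
  100 * fi / total_n
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (`0.125 -> 0.13` at two digits),
#' as used for reporting fragility quotients; base R's [round()] rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @export
print.fragility <- function(x, ...) {
  cat(sprintf("Fragility index: %d (fragility quotient %.2f%% of N = %d)\n",
              x$fi, round_half_up(x$fq_percent), x$n))
  cat(sprintf("Baseline Fisher p = %.4g (alpha = %g, %s convention)\n",
              x$baseline_p, x$alpha, x$convention))
  if (x$fi == 0L && x$baseline_p >= x$alpha) {
    cat("Not significant at baseline; no events added.\n")
  } else if (nrow(x$trace) > 0L) {
    cat(sprintf("Events added to the %s arm%s; final p = %.4g\n",
                x$modified_arm,
                if (x$converged) "" else " (arm saturated before p >= alpha)",
                x$final_p))
  }
  invisible(x)
}
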