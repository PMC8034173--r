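#' Build a 2x2 contingency table for a two-arm trial
#'
#' Cross-tabulates trial arm (experimental vs control) against a dichotomous
#' outcome (event vs non-event). This is the object the fragility-index
#' iteration operates on.
#'
#' @param exp_events Number of events in the experimental arm.
#' @param exp_total Experimental-arm sample size.
#' @param ctrl_events Number of events in the control arm.
#' @param ctrl_total Control-arm sample size.
#'
#' @return An object of class `"fragility_table"`: a list with components
#'   `experimental` and `control`, each a list with integer `events` and
#'   `total`.
#'
#' @examples
#' contingency_table(46, 140, 82, 140)
#' @export
contingency_table <- function(exp_events, exp_total, ctrl_events, ctrl_total) {
  arm_count <- function(events, total, arm) {
    if (length(events) != 1L || length(total) != 1L ||
        !is.finite(events) || !is.finite(total) ||
        events != as.integer(events) || total != as.integer(total)) {
      stop(sprintf("%s arm: events and total must be single integers", arm),
           call. = FALSE)
    }
    events <- as.integer(events)
    total <- as.integer(total)
    if (total < 1L) {
      stop(sprintf("%s arm: total must be a positive count", arm), call. = FALSE)
    }
    if (events < 0L || events > total) {
      stop(sprintf("%s arm: events must satisfy 0 <= events <= total (got %d of %d)",
                   arm, events, total), call. = FALSE)
    }
    list(events = events, total = total)
  }
  tab <- structure(
    list(experimental = arm_count(exp_events, exp_total, "experimental"),
         control = arm_count(ctrl_events, ctrl_total, "control")),
    class = "fragility_table"
  )
  if (grand_total(tab) < 2L) stop("grand total must be at least 2", call. = FALSE)
  tab
}

#' @export
print.fragility_table <- function(x, ...) {
  cat("2x2 contingency table (two-arm trial)\n")
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.fragility_table <- function(x, ...) {
  matrix(c(x$experimental$events, x$experimental$total - x$experimental$events,
           x$control$events, x$control$total - x$control$events),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("experimental", "control"),
                         c("event", "non-event")))
}

grand_total <- function(table) table$experimental$total + table$control$total

total_events <- function(table) table$experimental$events + table$control$events

#' Hypergeometric probability mass function
#'
#' Probability of drawing exactly `k` successes in `draws` draws without
#' replacement from a population of size `population` containing `successes`
#' successes. Computed in log space (via log binomial coefficients) so that
#' trial-scale counts never overflow. This is the sampling distribution of
#' one cell of a 2x2 table with all margins fixed, and underpins the exact
#' test.
#'
#' @param k Integer vector of success counts; every element must lie in the
#'   support `max(0, draws + successes - population) <= k <= min(draws, successes)`.
#' @param population Population size.
#' @param successes Number of successes in the population.
#' @param draws Number of draws.
#'
#' @return Numeric vector of probabilities, one per element of `k`.
#'
#' @examples
#' hypergeom_pmf(5, 10, 5, 5)  # 1/252
#' sum(hypergeom_pmf(0:5, 10, 5, 5))  # 1
#' @export
hypergeom_pmf <- function(k, population, successes, draws) {
  stopifnot(length(population) == 1L, length(successes) == 1L,
            length(draws) == 1L)
  if (successes < 0 || successes > population || draws < 0 || draws > population) {
    stop("require 0 <= successes <= population and 0 <= draws <= population",
         call. = FALSE)
  }
  lo <- max(0, draws + successes - population)
  hi <- min(draws, successes)
  if (any(k != floor(k)) || any(k < lo) || any(k > hi)) {
    stop(sprintf("k outside the hypergeometric support [%d, %d]", lo, hi),
         call. = FALSE)
  }
  exp(lchoose(successes, k) + lchoose(population - successes, draws - k) -
        lchoose(population, draws))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test of independence given the observed margins. The
#' two-sided p-value follows the minimum-likelihood convention: the sum of
#' hypergeometric probabilities of every table sharing the observed margins
#' whose probability does not exceed that of the observed table, with a
#' relative tolerance of `1e-7` absorbing floating-point ties (the convention
#' of mainstream exact-test implementations). All mass is accumulated from
#' log-space binomial coefficients.
#'
#' Degenerate margins (no events at all, or events in every patient) leave a
#' single admissible table; the test returns p = 1 with a warning rather than
#' erroring, so that fragility iteration over such tables terminates
#' gracefully.
#'
#' @param table A [contingency_table()].
#'
#' @return A list of class `"fisher_exact"` with components `p_two_sided` and
#'   `observed_table_probability`.
#'
#' @examples
#' fisher_exact(contingency_table(0, 5, 5, 5))  # p = 2/252
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "fragility_table"))
  n1 <- table$experimental$total
  n2 <- table$control$total
  m <- total_events(table)
  N <- n1 + n2
  if (m == 0L || m == N) {
    warning("degenerate margins (all-zero outcome column); p = 1", call. = FALSE)
    return(structure(list(p_two_sided = 1, observed_table_probability = 1),
                     class = "fisher_exact"))
  }
  support <- max(0L, m - n2):min(m, n1)
  pmf <- hypergeom_pmf(support, N, m, n1)
  p_obs <- pmf[match(table$experimental$events, support)]
  p <- min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
  structure(list(p_two_sided = p, observed_table_probability = p_obs),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat(sprintf("Fisher exact test (two-sided): p = %.6g\n", x$p_two_sided))
  invisible(x)
}
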