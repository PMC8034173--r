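# Shared fixtures and independent oracles.

# The six reference-cohort 2x2 tables as (exp_events, exp_total, ctrl_events,
# ctrl_total), with the fragility values as originally published.
table1_counts <- list(
  silius = c(37, 102, 18, 103),
  wang = c(46, 140, 82, 140),
  lee = c(69, 114, 59, 112),
  sharp = c(44, 299, 33, 303),
  wei = c(83, 116, 85, 118),
  geissler = c(242, 252, 234, 256)
)
table1_published_fi <- c(silius = 7, wang = 19, lee = 0, sharp = 0, wei = 0,
                         geissler = 1)

tab_from <- function(v) contingency_table(v[1], v[2], v[3], v[4])

grand_total_of <- function(tab) tab$experimental$total + tab$control$total

# Brute-force two-sided Fisher p: enumerate every 2x2 table with the observed
# margins, computing each table's probability directly from choose(), and sum
# the probabilities no larger than the observed table's. Independent of the
# package's log-space pmf path.
brute_fisher_p <- function(exp_events, exp_total, ctrl_events, ctrl_total) {
  m <- exp_events + ctrl_events
  N <- exp_total + ctrl_total
  ks <- max(0, m - ctrl_total):min(m, exp_total)
  probs <- choose(exp_total, ks) * choose(ctrl_total, m - ks) / choose(N, m)
  p_obs <- probs[ks == exp_events]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# (n+1)-position linear-interpolation quantile, written from the definition
# (sort, position p = (n+1)q, interpolate, clamp) as an oracle for quantile_n1.
brute_quantile_n1 <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  vapply(q, function(qq) {
    pos <- (n + 1) * qq
    if (pos <= 1) return(s[1])
    if (pos >= n) return(s[n])
    lo <- floor(pos)
    s[lo] + (pos - lo) * (s[lo + 1] - s[lo])
  }, numeric(1))
}
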