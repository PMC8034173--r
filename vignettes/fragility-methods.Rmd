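---
title: "Fragility analysis of two-arm randomized trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility analysis of two-arm randomized trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rctfragility)
```

## The question the fragility index answers

A randomized controlled trial reports a statistically significant dichotomous
result. How many individual patients stand between that result and
non-significance? The fragility index (FI) answers this literally: it is the
minimum number of patients in one arm whose status would have to flip from
non-event to event before a two-sided Fisher exact test on the trial's 2×2
table no longer rejects at level $\alpha$. An FI of 1 means a single patient's
outcome separates "the treatment works" from "no evidence of effect"; an FI of
19 means the conclusion can absorb substantial reclassification. The fragility
quotient (FQ) rescales the FI by the total sample size,
$\mathrm{FQ} = 100 \cdot \mathrm{FI} / N$ percent, so trials of different
sizes can be compared.

The method applies only to two-arm trials with 1:1 allocation and a
dichotomous end-of-study outcome. `fragility_summary()` refuses non-1:1
records rather than silently computing something ill-defined.

## The exact test

All significance assessments use Fisher's exact test. Conditioning on both
margins of the table

|              | event | non-event | total |
|--------------|-------|-----------|-------|
| experimental | $a$   | $n_1-a$   | $n_1$ |
| control      | $c$   | $n_2-c$   | $n_2$ |

the experimental event count follows a hypergeometric distribution, and the
two-sided p-value is taken by the minimum-likelihood convention: the sum of
probabilities of all tables with the same margins that are no more probable
than the observed one. A relative tolerance of $10^{-7}$ absorbs
floating-point ties in the "no more probable" comparison; this is the
convention of the mainstream exact-test implementations, including R's
`fisher.test`, with which the package's own `fisher_exact()` agrees to
numerical precision in the test suite. All probability mass is accumulated
from log binomial coefficients and exponentiated only at the end, so
trial-scale counts never overflow.

Two degenerate cases deserve note. If no patient in either arm has an event
(or every patient does), only one table is compatible with the margins; the
test returns $p = 1$ with a warning instead of erroring, so that batch runs
and the FI iteration terminate gracefully.

## The fragility iteration

`fragility()` implements the event-addition algorithm:

1. Compute the baseline two-sided Fisher p. If $p \ge \alpha$ the trial is
   not significant by this test and FI = 0. (In practice this happens to
   trials whose published significance came from a stratified log-rank test
   on the time-to-event outcome; Fisher on end-of-study counts is a
   different, and often less powerful, question.)
2. Otherwise add events one at a time — one non-event becomes an event, arm
   totals unchanged — to the **fewest-events arm**, re-selected after every
   step, recording the p-value after each addition.
3. Stop at the first step where $p \ge \alpha$. The number of additions is
   the FI.

Design choices embedded here, and why:

* **Arm convention.** The classical informal description says events are
  added to the experimental arm, but that phrasing only works when the
  experimental arm is the one with fewer events. When the treatment *increases*
  the event rate (e.g. response to therapy), adding events to the
  already-event-rich arm drives the p-value further down and can never
  nullify anything. The fewest-events convention — used by the popular web
  fragility calculators — is the one that makes the definition coherent for
  both orientations, and is the package default. For the SILIUS-style tables
  in the built-in cohort it is also the only convention that reproduces the
  published FI values. `"experimental"` and `"control"` remain available as
  explicit overrides, and forcing a saturated arm is reported as
  non-convergence rather than an error.
* **Nullification boundary.** Significance is defined as $p < \alpha$, so it
  is lost at $p \ge \alpha$; exact equality counts as nullified. Default
  $\alpha = 0.05$.
* **Re-selection each step.** Under the fewest-events convention the target
  arm is re-chosen after every addition. For realistic trial tables the
  fewer-events arm cannot overtake the other before the p-value crosses
  $\alpha$, so this matches the fixed-arm variant observationally, but it is
  the safer definition for adversarial inputs.
* **Saturation.** If the target arm runs out of non-events while still
  significant, the iteration returns `converged = FALSE` with the steps
  taken, plus a warning — batch analyses survive pathological rows.

The FI's defining minimality property — after $\mathrm{FI}-1$ additions the
table is still significant, after $\mathrm{FI}$ it is not — is re-verified in
the test suite on every built-in trial and on 600 simulated tables per run,
by independently replaying the additions rather than trusting the iteration's
own trace.

## Cohort summaries and the quantile convention

`fragility_summary()` aggregates per-trial results with medians and
interquartile ranges. Quantiles use **(n+1)-position linear interpolation**
(`stats::quantile` type 6): the $q$-quantile is the order statistic at
position $(n+1)q$, interpolated linearly between neighbours and clamped at
the extremes. This convention is common in clinical biostatistics software
(SPSS's default, among others) and is the one under which the built-in
cohort's published quartiles — a lower sample-size quartile of 220.75 and an
FI upper quartile of 10 from six values — are exactly reproducible; R's
default type 7 reproduces neither.

Fragility quotients are computed unrounded and rounded half-up (not half-even)
to two decimals only in report columns, matching how such tables are
conventionally printed.

## The built-in cohort

`hcc_trials()` carries six phase-3 hepatocellular-carcinoma RCTs with 1:1
allocation whose 2×2 outcome counts are published: SILIUS (sorafenib plus
hepatic arterial infusion chemotherapy), adjuvant TACE, adjuvant CIK-cell
immunotherapy, SHARP (sorafenib vs placebo), hepatectomy plus TACE, and
sirolimus after liver transplantation. Five contribute a primary endpoint,
one a secondary overall-survival endpoint. The `reported_p` column is the
significance level each publication reported — typically from a stratified
log-rank test — and is metadata only: it never enters any computation here,
because the FI is defined against the Fisher test, not against whatever test
the original authors used. That distinction is exactly why three of the five
primary-endpoint trials have FI = 0: their Fisher p on end-of-study counts
already exceeds 0.05.

One transcription note: the transplantation trial's registry identifier is
carried as printed in the source table, and its reported p-value cell is
empty there, so `reported_p` is `NA` for that row.

```{r cohort}
fragility_summary(hcc_trials())
```

## The synthetic trial generator

`simulate_trials()` emulates the statistical structure the fragility method
actually assumes: a two-arm 1:1 trial whose arms experience events as
independent binomial draws, $a \sim \mathrm{Bin}(n, \pi_E)$,
$c \sim \mathrm{Bin}(n, \pi_C)$, with no time axis. That is a deliberate
match to the analysis, which itself discards time-to-event structure —
Fisher's test sees only end-of-study counts. Consequently the generator does
*not* emulate censoring, variable follow-up, non-proportional hazards, or
stratified randomization; passing tests say nothing about how the FI behaves
relative to a log-rank analysis of real survival data, only that the
2×2-table machinery is correct.

The seed is mandatory (no implicit entropy) and the caller's RNG state is
restored afterwards, so simulated cohorts are bit-reproducible and
composable. Default experiment parameters for `fi_p_correlation()` are event
rates 0.5 vs 0.3 with 100 patients per arm — a large, deliberately
well-powered effect (power well above 50%) so that the significant subset on
which the FI–p rank correlation is computed is well populated — and 1000
trials. Only the *direction* of that correlation (negative: smaller p, larger
FI) is asserted anywhere; its magnitude depends strongly on the design and is
not a stable property. Fewer than 10 significant trials is reported as an
error rather than a meaningless correlation.

Problem sizes used by the test suite and analysis scripts — cohorts of
200–1000 trials at 40–200 patients per arm — were chosen as the smallest
sizes at which the Monte-Carlo assertions (type-I calibration within
$3\sqrt{\alpha(1-\alpha)/n}$ of $\alpha$, correlation direction, median-FI
monotonicity in $n$) are comfortably stable across seeds.

## Known limitations

* The FI is defined here only for 1:1 two-arm designs with dichotomous
  outcomes; no reverse FI for non-significant trials, no survival-time
  variant, no continuous outcomes.
* The cohort aggregates are descriptive (median/IQR); no pooling or
  meta-analytic weighting is attempted.
* The published table this cohort derives from contains two internally
  inconsistent percentages for the "FI ≤ 7" fraction; the package reports
  directly computed counts and does not attempt to reproduce inconsistent
  derived percentages. Likewise the upper quartile of the six sample sizes
  under the (n+1) convention is 531.5, which the package reports as computed.
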