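# rctfragility

How robust is a statistically significant randomized-trial result? The
**fragility index (FI)** answers in patients: it is the minimum number of
participants in one arm of a two-arm 1:1 trial whose status would have to
flip from non-event to event before a two-sided Fisher exact test on the
trial's 2×2 table loses significance at level α. The **fragility quotient
(FQ)** scales it by trial size, FQ = 100·FI/N percent. A trial with FI = 1
hangs its conclusion on a single patient's outcome; FI = 0 means the result
is not even significant under the Fisher test (common when the published
p-value came from a stratified log-rank test on the time-to-event outcome).

The package is aimed at clinical meta-researchers and trial methodologists.
It provides:

- `hypergeom_pmf()`, `fisher_exact()` — first-principles exact-test
  machinery: the hypergeometric law of one cell of a margin-fixed 2×2 table,
  accumulated in log space, and the minimum-likelihood two-sided p
  (sum of probabilities of all same-margin tables no more probable than the
  observed one);
- `fragility()` — the FI iteration (event added to the fewest-events arm,
  re-selected each step, until p ≥ α), with full step trace, plus
  `fragility_quotient()`;
- `fragility_summary()` — cohort-level analysis with median/IQR aggregation
  under (n+1)-position quantile interpolation (`quantile_n1()`);
- `hcc_trials()` — a built-in reference cohort of six phase-3
  hepatocellular-carcinoma RCTs with published 2×2 counts, including the
  originally published FI/FQ values for side-by-side checks;
- `read_trials()` / `write_trials()` / `write_summary()` — CSV/JSON exchange
  in a documented schema (a copy of the cohort ships at
  `inst/extdata/table1.csv`);
- `simulate_trials()`, `fi_p_correlation()` — a seeded binomial trial
  simulator for calibration studies and for the FI–p relationship.

## Worked example

```r
library(rctfragility)

# adjuvant-TACE trial: 46/140 events vs 82/140
fragility(contingency_table(46, 140, 82, 140))
#> Fragility index: 19 (fragility quotient 6.79% of N = 280)
#> Baseline Fisher p = 2.436e-05 (alpha = 0.05, fewest_events convention)
#> Events added to the experimental arm; final p = 0.05533

fragility_summary(hcc_trials())
#> Fragility analysis of 6 trials (alpha = 0.05, fewest_events convention)
#>
#>          study_label endpoint_rank   n fi fq_percent baseline_p
#>   Kudo 2018 (SILIUS)       primary 205  7       3.41   2.74e-03
#>            Wang 2018       primary 280 19       6.79   2.44e-05
#>             Lee 2015       primary 226  0       0.00   2.83e-01
#>  Llovet 2008 (SHARP)       primary 602  0       0.00   1.80e-01
#>             Wei 2018       primary 234  0       0.00   1.00e+00
#>        Geissler 2016     secondary 508  1       0.20   4.33e-02
#>
#> Median FI 0.5 (IQR 0-10); median N 257 (IQR 220.75-531.5)
#> 3 of 5 primary-endpoint trials have FI = 0 (baseline Fisher p >= alpha)
```

Reading this: the adjuvant-TACE trial tolerates 19 patient-level
reclassifications before losing significance (the most robust of the six),
while half the cohort has FI = 0 — their recurrence/survival findings were
significant by log-rank but not by an exact test on end-of-study counts. An
FI at or below 1% of the sample size (FQ ≤ 1%) is conventionally read as
fragile.

Half the cohort's published quartiles are only reproducible under the
(n+1)-position quantile convention (`stats::quantile` type 6); the source
table also contains two internally inconsistent derived percentages, which
this package does not reproduce — it always reports directly computed
counts. See the methods vignette (`vignettes/fragility-methods.Rmd`) for the
conventions and their rationale.

## Analysis scripts

- `analysis/01_reproduce_cohort.R` — runs the full cohort analysis, prints a
  computed-vs-published FI/FQ side-by-side (all six trials match), and
  writes per-trial and aggregate tables under `results/`.
- `analysis/02_simulation_properties.R` — seeded simulation studies: type-I
  calibration of the FI under equal event rates, the negative FI–p rank
  correlation among significant trials, and the growth of the median FI with
  sample size.

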