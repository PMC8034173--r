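test_that("select_target_arm picks the fewest-events arm, ties to experimental", {
  expect_identical(select_target_arm(tab_from(table1_counts$silius)), "control")
  expect_identical(select_target_arm(tab_from(table1_counts$wang)), "experimental")
  expect_identical(select_target_arm(contingency_table(10, 50, 10, 50)),
                   "experimental")
  expect_identical(select_target_arm(tab_from(table1_counts$silius), "experimental"),
                   "experimental")
  expect_identical(select_target_arm(tab_from(table1_counts$wang), "control"),
                   "control")
})

test_that("add_event flips one non-event and preserves totals", {
  tab <- tab_from(table1_counts$silius)
  out <- add_event(tab, "control")
  expect_identical(out$control$events, 19L)
  expect_identical(out$experimental$events, 37L)
  expect_identical(grand_total_of(out), grand_total_of(tab))

  # repeated application never changes N
  cur <- tab
  for (i in 1:10) cur <- add_event(cur, "experimental")
  expect_identical(grand_total_of(cur), 205L)
  expect_identical(cur$experimental$events, 47L)

  expect_error(add_event(contingency_table(5, 5, 0, 5), "experimental"),
               class = "fragility_saturation")
})

test_that("fragility reproduces the published reference-cohort indices", {
  for (nm in names(table1_counts)) {
    f <- fragility(tab_from(table1_counts[[nm]]))
    expect_identical(f$fi, as.integer(table1_published_fi[[nm]]))
    expect_true(f$converged)
  }
})

test_that("fragility result is internally consistent", {
  f <- fragility(tab_from(table1_counts$wang))
  expect_identical(f$fi, 19L)
  expect_identical(nrow(f$trace), f$fi)
  expect_lt(f$baseline_p, 0.05)
  expect_true(all(f$trace$p[-f$fi] < 0.05))
  expect_gte(f$trace$p[f$fi], 0.05)
  expect_identical(f$final_p, f$trace$p[f$fi])
  expect_identical(f$modified_arm, "experimental")
  expect_equal(f$fq_percent, 100 * 19 / 280)

  # FI = 0 path: baseline already non-significant, nothing modified
  f0 <- fragility(tab_from(table1_counts$lee))
  expect_identical(f0$fi, 0L)
  expect_gte(f0$baseline_p, 0.05)
  expect_identical(f0$modified_arm, "none")
  expect_identical(nrow(f0$trace), 0L)
  expect_identical(f0$final_p, f0$baseline_p)

  # identical arms: p = 1 at baseline
  expect_identical(fragility(contingency_table(20, 100, 20, 100))$fi, 0L)
})

test_that("fragility is deterministic", {
  a <- fragility(tab_from(table1_counts$silius))
  b <- fragility(tab_from(table1_counts$silius))
  expect_identical(a, b)
})

test_that("saturation yields converged = FALSE with the steps taken", {
  # lopsided table: significant at baseline, yet the fewest-events arm (the
  # tie goes to the fully-evented experimental arm) has no non-event to flip
  tab <- contingency_table(3, 3, 3, 20)
  expect_lt(fisher_exact(tab)$p_two_sided, 0.05)
  expect_warning(f <- fragility(tab), "saturat")
  expect_false(f$converged)
  expect_identical(f$fi, nrow(f$trace))
  expect_lt(f$final_p, 0.05)
})

test_that("forcing the larger-events arm cannot nullify SILIUS", {
  # the experimental arm already carries the excess events; adding more there
  # only strengthens significance until the arm saturates
  expect_warning(f <- fragility(tab_from(table1_counts$silius),
                                convention = "experimental"), "saturat")
  expect_false(f$converged)
})

test_that("alpha is honoured", {
  tab <- tab_from(table1_counts$geissler)  # baseline p ~ 0.043
  expect_identical(fragility(tab, alpha = 0.05)$fi, 1L)
  expect_identical(fragility(tab, alpha = 0.01)$fi, 0L)
  expect_gt(fragility(tab, alpha = 0.2)$fi, 1L)
  expect_error(fragility(tab, alpha = 0), "alpha")
  expect_error(fragility(tab, alpha = 1), "alpha")
})

test_that("fragility_quotient and half-up rounding match reporting rules", {
  expect_equal(fragility_quotient(19, 280), 6.785714285714286)
  expect_equal(round_half_up(fragility_quotient(19, 280)), 6.79)
  expect_equal(round_half_up(fragility_quotient(7, 205)), 3.41)
  expect_equal(fragility_quotient(0, 1000), 0)
  expect_equal(round_half_up(0.125, 2), 0.13)  # half goes up, not to even
  expect_error(fragility_quotient(-1, 100), "non-negative")
  expect_error(fragility_quotient(3, 1), "at least 2")
})

test_that("FI minimality holds across random synthetic tables", {
  # the defining property: FI - 1 additions leave p < alpha, FI additions
  # reach p >= alpha. Rebuilt step by step, independently of the trace.
  trials <- simulate_trials(40, 0.55, 0.2, n_trials = 700, seed = 2024)
  checked <- 0L
  for (i in seq_len(nrow(trials))) {
    tab <- contingency_table(trials$exp_events[i], trials$exp_total[i],
                             trials$ctrl_events[i], trials$ctrl_total[i])
    if (fisher_exact(tab)$p_two_sided >= 0.05) next
    f <- suppressWarnings(fragility(tab))
    if (!f$converged) next
    cur <- tab
    for (k in seq_len(f$fi - 1L)) {
      cur <- add_event(cur, select_target_arm(cur))
      expect_lt(fisher_exact(cur)$p_two_sided, 0.05)
    }
    cur <- add_event(cur, select_target_arm(cur))
    expect_gte(fisher_exact(cur)$p_two_sided, 0.05)
    checked <- checked + 1L
  }
  expect_gte(checked, 500L)
})
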