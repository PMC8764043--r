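ref <- load_reference_cohort()
calls <- counts_to_calls(ref$counts)
vars <- reference_variants(ref$counts)

test_that("reference counts conserve the cohort totals", {
  expect_equal(nrow(calls), 97)
  expect_equal(nrow(vars), 26)
  expect_equal(sum(calls$tissue == "BREAST"), 90)
  expect_equal(sum(calls$tissue == "OVARY"), 7)
  expect_equal(as.vector(table(vars$classification)[c("PATHOGENIC", "VUS")]),
               c(10L, 8L))
  expect_equal(sum(vars$classification %in% c("BENIGN", "LIKELY_BENIGN")), 8)
})

test_that("per-variant rows reproduce the published counts and renderings", {
  rows <- summarize_by_variant(calls, vars, tissue = "BREAST")
  r <- rows[rows$variant_id == "c.68_69del", ]
  expect_equal(c(r$n_balance, r$n_loss_variant, r$n_loss_wt, r$n_total),
               c(2, 0, 7, 9))
  expect_equal(r$pct_imbalance_render, 78L)
  expect_equal(r$pct_loss_wt_render, 100L)
  # the largest breast series
  r2 <- rows[rows$variant_id == "c.5266dup", ]
  expect_equal(c(r2$n_balance, r2$n_loss_variant, r2$n_loss_wt, r2$n_total),
               c(3, 1, 13, 17))
  # no imbalanced sample: loss-of-WT percentage undefined
  r3 <- rows[rows$variant_id == "c.5453A>G", ]
  expect_equal(r3$pct_imbalance, 0)
  expect_true(is.na(r3$pct_loss_wt_of_imbalanced))
  # recurrent VUS rows (breast + ovary combined)
  rows_all <- summarize_by_variant(calls, vars)
  v1 <- rows_all[rows_all$variant_id == "c.4963T>C", ]
  expect_equal(c(v1$n_balance, v1$n_loss_variant, v1$n_loss_wt, v1$n_total),
               c(1, 0, 4, 5))
  expect_equal(v1$pct_imbalance_render, 80L)
  expect_equal(v1$pct_loss_wt_render, 100L)
  v2 <- rows_all[rows_all$variant_id == "c.5497G>A", ]
  expect_equal(c(v2$n_loss_wt, v2$n_total), c(3, 3))
  expect_equal(v2$pct_imbalance_render, 100L)
  expect_error(summarize_by_variant(dplyr::mutate(calls, variant_id = "nope"),
                                    vars),
               "unknown variants")
})

test_that("class totals pool member variants and conserve counts", {
  rows <- summarize_by_variant(calls, vars, tissue = "BREAST")
  cls <- summarize_by_class(rows)
  p <- cls[cls$class_group == "pathogenic", ]
  expect_equal(c(p$n_balance, p$n_loss_variant, p$n_loss_wt, p$n_total),
               c(16, 3, 32, 51))
  expect_equal(p$pct_imbalance_render, 69L)
  expect_equal(p$pct_loss_wt_render, 91L)
  b <- cls[cls$class_group == "benign", ]
  expect_equal(c(b$n_balance, b$n_loss_variant, b$n_loss_wt, b$n_total),
               c(17, 4, 5, 26))
  expect_equal(b$pct_imbalance_render, 35L)
  expect_equal(b$pct_loss_wt_render, 56L)
  # conservation: class totals equal sums over member rows
  expect_equal(sum(cls$n_total), sum(rows$n_total))
  expect_equal(sum(cls$n_loss_wt), sum(rows$n_loss_wt))
})

test_that("a variant with a single balanced tumor renders 0% imbalance", {
  one <- tibble::tibble(sample_id = "s", variant_id = "v", tissue = "BREAST",
                        status = "BALANCE")
  v <- tibble::tibble(variant_id = "v", classification = "VUS",
                      effect = "MISSENSE")
  row <- summarize_by_variant(one, v)
  expect_equal(row$pct_imbalance, 0)
  expect_true(is.na(row$pct_loss_wt_of_imbalanced))
})

test_that("loss-of-WT predicts pathogenicity with the published confusion counts", {
  perf <- predictor_performance(calls, vars)
  expect_equal(c(perf$tp, perf$fn, perf$fp, perf$tn), c(36, 19, 6, 21))
  expect_equal(perf$sensitivity_render, 65L)
  expect_equal(perf$specificity_render, 78L)
  # the one-decimal pathogenic rate truncates to the published 65.4
  expect_equal(trunc(perf$sensitivity * 10) / 10, 65.4)
  # a perfectly separated cohort
  toy_calls <- tibble::tibble(
    sample_id = c("a", "b"), variant_id = c("p", "b"),
    tissue = "BREAST", status = c("LOSS_WT", "BALANCE"))
  toy_vars <- tibble::tibble(variant_id = c("p", "b"),
                             classification = c("PATHOGENIC", "BENIGN"),
                             effect = "MISSENSE")
  toy <- predictor_performance(toy_calls, toy_vars)
  expect_equal(c(toy$sensitivity, toy$specificity), c(100, 100))
  expect_error(predictor_performance(toy_calls[1, ], toy_vars),
               "at least one")
})

test_that("performance recovers the generative rates on a simulated cohort", {
  cfg <- simulation_config(
    n_variants_per_class = 5, samples_per_variant = 200,
    p_loss_wt_by_class = c(PATHOGENIC = 0.654, BENIGN = 0.222),
    p_loss_variant_by_class = c(PATHOGENIC = 0.055, BENIGN = 0.148),
    purity_range = c(0.6, 0.95), read_depth = 500, method = "NGS",
    seed = 77)
  co <- simulate_cohort(cfg)
  perf <- predictor_performance(call_cohort(co), co$variants)
  expect_lt(abs(perf$sensitivity - 65.4), 5)
  expect_lt(abs(perf$specificity - 77.8), 5)
})

test_that("2x2 chi-squared matches the closed form and its scaling property", {
  got <- class_association_test(c(36, 19), c(6, 21))
  expect_equal(got$chi2, chi2_2x2(36, 19, 6, 21))
  expect_equal(got$p, pchisq(got$chi2, df = 1, lower.tail = FALSE))
  expect_lt(got$p, 0.001)
  # identical rows carry no association
  same <- class_association_test(c(10, 5), c(10, 5))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # doubling all counts doubles the statistic
  doubled <- class_association_test(c(72, 38), c(12, 42))
  expect_equal(doubled$chi2, 2 * got$chi2)
  expect_error(class_association_test(c(0, 0), c(1, 2)), "margin")
  expect_error(class_association_test(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("effect stratification shows more WT loss for truncating than missense variants", {
  eff <- effect_stratified_summary(calls, vars)
  m <- eff$by_group[eff$by_group$group == "missense", ]
  t <- eff$by_group[eff$by_group$group == "truncating", ]
  expect_gt(t$pct_loss_wt, m$pct_loss_wt)
  # the reported contrast was not statistically significant
  expect_gt(eff$test$p, 0.05)
  # all-missense input leaves the truncating group absent and no test
  ms_only <- effect_stratified_summary(
    calls[calls$variant_id == "c.181T>G", ], vars)
  expect_false("truncating" %in% ms_only$by_group$group)
  expect_null(ms_only$test)
})

test_that("the effect contrast controls its type-I error under the null", {
  # equal loss-of-WT rates in both effect groups, cohort-sized groups
  set.seed(404)
  n_sim <- 200
  false_pos <- 0
  for (i in seq_len(n_sim)) {
    k1 <- rbinom(1, 22, 0.6); k2 <- rbinom(1, 33, 0.6)
    tab_ok <- (k1 + k2) > 0 && (55 - k1 - k2) > 0
    p <- if (tab_ok) {
      class_association_test(c(k2, 33 - k2), c(k1, 22 - k1))$p
    } else 1
    if (p < 0.05) false_pos <- false_pos + 1
  }
  expect_lte(false_pos / n_sim, 0.10)
})
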