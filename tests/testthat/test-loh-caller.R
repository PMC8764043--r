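test_that("replicate aggregation returns mean and sample sd", {
  expect_equal(aggregate_replicates(c(0.65, 0.65, 0.65)), list(mean = 0.65, sd = 0))
  # hand computation: mean 0.65, sd = sqrt(((-.05)^2 + 0 + .05^2)/2) = 0.05
  agg <- aggregate_replicates(c(0.60, 0.65, 0.70))
  expect_equal(agg$mean, 0.65)
  expect_equal(agg$sd, 0.05)
  expect_equal(aggregate_replicates(0.49), list(mean = 0.49, sd = 0))
  expect_error(aggregate_replicates(numeric(0)), "at least one")
  expect_error(aggregate_replicates(c(NA, NA)), "at least one")
})

test_that("replicate t-test matches the textbook pooled computation and is symmetric", {
  x <- c(0.65, 0.66, 0.64)
  y <- c(0.50, 0.51, 0.50)
  got <- replicate_t_test(x, y)
  want <- pooled_t(x, y)
  expect_equal(got$t_statistic, want$t)
  expect_equal(got$p_value, want$p)
  expect_lt(got$p_value, 0.01)
  swapped <- replicate_t_test(y, x)
  expect_equal(swapped$t_statistic, -got$t_statistic)
  expect_equal(swapped$p_value, got$p_value)
  # identical constant groups: no imbalance evidence
  same <- replicate_t_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(replicate_t_test(0.5, c(0.5, 0.5)), ">= 2")
})

test_that("the imbalance rule is strict at the 10% boundary", {
  expect_equal(call_allelic_status(0.65, 0.50)$status, "LOSS_WT")
  expect_equal(call_allelic_status(0.49, 0.50)$status, "BALANCE")
  expect_equal(call_allelic_status(0.60, 0.50)$status, "BALANCE")
  expect_equal(call_allelic_status(0.601, 0.50)$status, "LOSS_WT")
  expect_equal(call_allelic_status(0.40, 0.50)$status, "BALANCE")
  expect_equal(call_allelic_status(0.399, 0.50)$status, "LOSS_VARIANT")
  expect_error(call_allelic_status(1.2, 0.5), "fraction")
  expect_error(call_allelic_status(0.5, 0.5, threshold = 0.6), "0, 0.5")
})

test_that("the caller is an exact function of (VAF, reference, threshold): grid oracle", {
  grid <- seq(0, 1, by = 0.001)
  for (thr in c(0.05, 0.10, 0.25)) {
    got <- call_allelic_status(grid, 0.5, thr)$status
    want <- ifelse(grid - 0.5 > thr, "LOSS_WT",
                   ifelse(grid - 0.5 < -thr, "LOSS_VARIANT", "BALANCE"))
    expect_identical(got, want)
  }
})

test_that("reflecting the VAF about the reference swaps the loss labels", {
  set.seed(20)
  vaf <- runif(500)
  ref <- 0.5
  a <- call_allelic_status(vaf, ref)$status
  b <- call_allelic_status(pmin(pmax(2 * ref - vaf, 0), 1), ref)$status
  expect_identical(b == "LOSS_WT", a == "LOSS_VARIANT")
  expect_identical(b == "LOSS_VARIANT", a == "LOSS_WT")
  expect_identical(b == "BALANCE", a == "BALANCE")
})

test_that("read-depth calls report VAF = alt/total with depth QC", {
  got <- call_from_reads(88, 100, 0.5, 0.10, 50)
  expect_equal(got$status, "LOSS_WT")
  expect_equal(got$tumor_vaf, 0.88)
  expect_equal(got$qc_flags, "")
  expect_equal(call_from_reads(50, 100)$status, "BALANCE")
  low <- call_from_reads(30, 100, 0.5, 0.10, min_depth = 200)
  expect_equal(low$status, "LOSS_VARIANT")
  expect_equal(low$qc_flags, "LOW_DEPTH")
  expect_error(call_from_reads(1, 0), "positive")
  expect_error(call_from_reads(12, 10), "alt_depth")
})

test_that("sample dispatch routes by method and sets reference/QC flags", {
  expect_equal(call_sample(pyro_sample(c(0.5, 0.5, 0.5)))$status, "BALANCE")
  # germline reference absent: fall back to 0.5, flagged
  s <- pyro_sample(c(0.72, 0.70, 0.71), germline_vaf = NA_real_)
  got <- call_sample(s)
  expect_equal(got$status, "LOSS_WT")
  expect_match(got$qc_flags, "NO_GERMLINE_REFERENCE")
  # low cellularity flagged but still called
  got2 <- call_sample(pyro_sample(c(0.5, 0.51, 0.49), cellularity = 0.2))
  expect_match(got2$qc_flags, "LOW_CELLULARITY")
  expect_equal(got2$status, "BALANCE")
  # NGS dispatch
  got3 <- call_sample(ngs_sample(880, 1000))
  expect_equal(got3$status, "LOSS_WT")
  # cohort path agrees with per-sample path
  samples <- dplyr::bind_rows(
    pyro_sample(c(0.65, 0.66, 0.64), sample_id = "a"),
    ngs_sample(30, 100, sample_id = "b", cellularity = 0.1))
  cc <- call_cohort(samples)
  expect_identical(cc$status, c("LOSS_WT", "LOSS_VARIANT"))
  expect_identical(cc$status,
                   c(call_sample(samples[1, ])$status,
                     call_sample(samples[2, ])$status))
  expect_equal(cc$qc_flags[2], "LOW_CELLULARITY")
})

test_that("a simulated deletion LOH at purity 0.9 and high depth is called", {
  # expected VAF 1/1.1 = 0.909, delta 0.409 >> 0.10
  s <- withr::with_seed(8, ngs_sample(rbinom(1, 1e4, 1 / 1.1), 1e4))
  expect_equal(call_sample(s)$status, "LOSS_WT")
})

test_that("loss-of-WT sensitivity rises with purity and with read depth", {
  sens <- function(purity_hi, depth) {
    cfg <- simulation_config(
      n_variants_per_class = 2, samples_per_variant = 150,
      p_loss_wt_by_class = c(PATHOGENIC = 1),
      p_loss_variant_by_class = c(PATHOGENIC = 0),
      purity_range = c(0.05, purity_hi), read_depth = depth,
      method = "NGS", seed = 31)
    co <- simulate_cohort(cfg)
    calls <- call_cohort(co)
    mean(calls$status == "LOSS_WT")
  }
  by_purity <- c(sens(0.35, 200), sens(0.65, 200), sens(0.95, 200))
  expect_true(all(diff(by_purity) >= 0))
  # depth tightens the VAF draw around a detectable expectation; monotone
  # once the expected delta clears the threshold (purity above 1/3)
  sens_detectable <- function(depth) {
    cfg <- simulation_config(
      n_variants_per_class = 2, samples_per_variant = 150,
      p_loss_wt_by_class = c(PATHOGENIC = 1),
      p_loss_variant_by_class = c(PATHOGENIC = 0),
      purity_range = c(0.40, 0.90), read_depth = depth,
      method = "NGS", seed = 31)
    mean(call_cohort(simulate_cohort(cfg))$status == "LOSS_WT")
  }
  by_depth <- c(sens_detectable(20), sens_detectable(150),
                sens_detectable(2000))
  expect_true(all(diff(by_depth) >= 0))
})

test_that("caller recovers the generative loss-of-WT rate on a detectable cohort", {
  cfg <- simulation_config(
    n_variants_per_class = 5, samples_per_variant = 100,
    p_loss_wt_by_class = c(PATHOGENIC = 0.654),
    p_loss_variant_by_class = c(PATHOGENIC = 0.055),
    purity_range = c(0.6, 0.95), read_depth = 500,
    method = "NGS", seed = 2024)
  co <- simulate_cohort(cfg)
  calls <- call_cohort(co)
  expect_lt(abs(mean(calls$status == "LOSS_WT") - 0.654), 0.05)
})
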