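#!/usr/bin/env Rscript
# Synthetic-cohort validation of the calling and summary pipeline: simulate
# carrier cohorts with a latent second-hit event under the reference
# generative rates, call allelic status, and check what the caller
# recovers as a function of tumor purity.
#
# Finds: at detectable purity (>= 0.6) and depth 500 the caller recovers
# the pathogenic loss-of-WT rate 0.654 within sampling error, and class
# separation (sensitivity/specificity) matches the reference cohort. Under
# the cohort-wide purity range 0.3-0.9, purities below the deletion
# detectability bound (1/3) convert true WT-loss events into balanced
# calls, depressing sensitivity — the same false-negative mode seen in the
# low-cellularity family tumor.

suppressMessages({
  library(brca1loh)
  library(dplyr)
  library(readr)
})

dir.create("results", showWarnings = FALSE)

base <- read_simulation_config(
  system.file("extdata", "sim_config.yaml", package = "brca1loh"))

# detectable regime: purity >= 0.6, NGS depth 500
cfg_det <- simulation_config(
  n_variants_per_class = 5, samples_per_variant = 200,
  p_loss_wt_by_class = base$p_loss_wt_by_class,
  p_loss_variant_by_class = base$p_loss_variant_by_class,
  purity_range = c(0.6, 0.95), read_depth = 500, method = "NGS",
  seed = base$seed)
co <- simulate_cohort(cfg_det)
calls <- call_cohort(co)
truth_path <- co$samples |>
  left_join(co$variants, by = "variant_id") |>
  filter(classification == "PATHOGENIC")
calls_path <- calls |> filter(sample_id %in% truth_path$sample_id)
recovered <- mean(calls_path$status == "LOSS_WT")
perf <- predictor_performance(calls, co$variants)
write_tsv(perf, "results/sim_performance_detectable.tsv")

cat(sprintf("detectable regime (purity 0.6-0.95, depth 500, %d pathogenic samples):\n",
            nrow(calls_path)))
cat(sprintf("  recovered pathogenic loss-of-WT rate %.3f (generative 0.654)\n",
            recovered))
cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
            perf$sensitivity, perf$specificity))

# purity sweep: caller sensitivity for a certain WT-loss event
sweep <- bind_rows(lapply(seq(0.1, 0.9, by = 0.1), function(pur) {
  cfg <- simulation_config(
    n_variants_per_class = 2, samples_per_variant = 250,
    p_loss_wt_by_class = c(PATHOGENIC = 1),
    p_loss_variant_by_class = c(PATHOGENIC = 0),
    purity_range = c(pur, pur), read_depth = base$read_depth,
    method = "NGS", seed = base$seed + round(100 * pur))
  cc <- call_cohort(simulate_cohort(cfg))
  tibble(purity = pur, sensitivity = mean(cc$status == "LOSS_WT"),
         expected_vaf = expected_vaf("LOSS_WT", pur, base$copy_model))
}))
write_tsv(sweep, "results/sim_purity_sweep.tsv")
cat("\nsensitivity for a deletion-type WT loss by purity:\n")
print(as.data.frame(sweep), digits = 3)
cat("the crossing near purity 1/3 is the analytic detectability bound at the 0.10 threshold\n")
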