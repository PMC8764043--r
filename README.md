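# brca1loh

Loss-of-heterozygosity (LOH) evidence for germline *BRCA1* variant
classification.

*BRCA1* is a tumor suppressor: tumors arising in carriers of a pathogenic
germline variant usually inactivate the remaining wild-type (WT) allele,
most often by LOH, so the variant-allele fraction (VAF) in tumor DNA rises
above the heterozygous germline expectation of 0.5. Benign variants show
LOH less often, and which allele is lost is closer to random. A single
tumor can never classify a variant — WT loss happens by chance in benign
carriers too — but *recurrent* WT loss across independent tumors carrying
the same variant is quantifiable evidence. This package is for clinical
genetics and variant-curation work that wants that evidence computed,
calibrated, and reproducible.

Four stages, each a small set of tested functions:

1. **Calling** (`call_allelic_status`, `call_from_reads`, `call_cohort`):
   a tumor is called loss-of-WT / loss-of-variant / balance by the strict
   10% rule, `|VAF_tumor − VAF_reference| > 0.10`, from pyrosequencing
   replicates (mean-aggregated, with a replicate *t*-test as QC) or NGS
   read depths; QC flags for low depth, low cellularity, missing germline.
2. **Summarizing** (`summarize_by_variant`, `summarize_by_class`,
   `predictor_performance`, `class_association_test`): per-variant and
   per-class LOH patterns, sensitivity/specificity of WT loss as a
   pathogenicity predictor, 2×2 chi-squared class association.
3. **Binomial evidence** (`loh_evidence`, `decision_table`,
   `classify_by_loh`): the loss-of-WT count among *n* tumors is
   *X* ~ B(*n*, *p*) with class-conditional *p*; exact tails
   P(X ≥ k | p_benign) and P(X ≤ k | p_pathogenic) grade the evidence and
   yield minimum-sample decision tables.
4. **Multifactorial posterior** (`combine_odds`, `posterior_probability`,
   `posterior_tier`, `classify_variant`): external likelihood ratios
   (co-segregation, pathology, family history) multiply into odds for
   causality; logit(posterior) = logit(prior) + log(odds); the posterior
   maps to the 5-tier classification.

A synthetic-cohort simulator (`simulate_cohort`) generates carrier cohorts
with the latent second-hit structure (purity-diluted expected VAFs under
deletion or copy-neutral LOH, binomial read noise or Gaussian replicate
noise) for end-to-end validation, and the published 97-tumor reference
cohort ships as packaged counts (`load_reference_cohort`).

## Worked example

Five tumors from one family segregate the (initially unclassified) variant
c.4963T>C. Call them, weigh the recurrence, and classify:

```r
library(brca1loh)
ref <- load_reference_cohort()

call_cohort(ref$family1)[, c("sample_id", "tumor_vaf", "status")]
#> # A tibble: 5 × 3
#>   sample_id tumor_vaf status
#>   <chr>         <dbl> <chr>
#> 1 F1-P1-T1       0.65 LOSS_WT
#> 2 F1-P1-T2       0.49 BALANCE
#> 3 F1-P2-T1       0.88 LOSS_WT
#> 4 F1-P2-T2       0.67 LOSS_WT
#> 5 F1-P3-T1       0.7  LOSS_WT
```

Four of five tumors lost the WT allele (the balanced one had 30% tumor
cellularity — below the purity where a deletion-type LOH is detectable at
the 10% rule). How surprising would that be for a benign variant, whose
per-tumor WT-loss rate in breast tumors is 5/26?

```r
loh_evidence(4, 5, p_benign = 5/26, p_pathogenic = 36/55)$prob_ge_k_given_benign
#> [1] 0.005786367
classify_by_loh(4, 5, p_benign = 5/26)
#> [1] "EXCLUDE_NEUTRALITY_MODERATE"
```

About 0.6% — moderate evidence against neutrality (strong would need all
five: P(5/5 | benign) = 0.026%, below the strict 0.05% risk). Adding the
family's external likelihood ratios:

```r
classify_variant("c.4963T>C",
                 c(cosegregation = 68.44, pathology = 152.88,
                   family_history = 8.71), prior = 0.03)
#> # A tibble: 1 × 6
#>   variant_id prior lr_components combined_odds posterior  tier
#>   <chr>      <dbl> <list>                <dbl>     <dbl> <int>
#> 1 c.4963T>C   0.03 <dbl [3]>            91134.     1.000     5
```

Posterior 0.99965 → tier 5, pathogenic.

## Analysis workflow

The `analysis/` scripts run the full study over the package functions and
write their tables under `results/`:

| script | what it computes |
|---|---|
| `01_reference_cohort.R` | per-variant/class LOH summaries, predictor performance, class association, effect stratification |
| `02_family_calls.R` | allelic-status calls for the worked family |
| `03_binomial_design.R` | strict and standard minimum-sample decision tables, evidence for the recurrent VUS |
| `04_multifactorial.R` | posterior probabilities and tiers for the two worked variants |
| `05_simulation.R` | synthetic-cohort parameter recovery and the purity detectability sweep |

Run any of them from the repository root, e.g.
`Rscript analysis/01_reference_cohort.R`.

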