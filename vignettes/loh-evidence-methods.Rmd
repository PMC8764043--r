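---
title: "LOH patterns as classification evidence: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LOH patterns as classification evidence: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brca1loh)
library(dplyr)
```

## The problem

BRCA1 is a tumor suppressor: in carriers of a germline pathogenic variant,
tumors typically inactivate the remaining wild-type (WT) allele, most often
by loss of heterozygosity (LOH). In tumor DNA this shows up as allelic
imbalance — the variant-allele fraction (VAF) drifts away from the
heterozygous germline expectation of 0.5. Which allele is lost is
informative: pathogenic variants preferentially lose the WT allele (the
VAF rises), while for benign variants LOH is less frequent and the lost
allele is close to random. A single tumor is never decisive — LOH of the
WT allele also occurs in carriers of benign variants — so the useful
signal is *recurrence*: repeated WT loss across independent tumors
carrying the same variant.

`brca1loh` implements that chain of reasoning as four testable stages:
calling allelic status from measured allele fractions, summarizing call
patterns per variant and per classification class, scoring recurrence with
a binomial evidence model, and folding external likelihood ratios into a
posterior probability of pathogenicity with a 5-tier class.

## Allelic-status calling

A tumor is compared against its germline reference VAF (0.5 when no
germline measurement is available, flagged `NO_GERMLINE_REFERENCE`). With
`delta = tumor_vaf - reference_vaf` and threshold `t` (default 0.10):

* `delta > t` — loss of the WT allele (variant enriched),
* `delta < -t` — loss of the variant allele,
* otherwise — allelic balance.

The inequality is strict: an imbalance of exactly 10 percentage points is
balance. The rule operates in absolute VAF units, not in a ratio of
ratios; this interpretation reproduces every reference call, including a
49% VAF calling "no LOH". Pyrosequencing samples aggregate replicates by
their mean (the replicate t-test against a non-carrier control is computed
and reported as QC metadata, but the threshold rule alone decides —
whether the original protocol additionally required test significance is
not documented, so the conservative choice is to keep the deterministic
rule). NGS samples use `alt_depth / total_depth`, with a `LOW_DEPTH` flag
below `min_depth` (default 50). Samples with cellularity below 0.30 are
flagged `LOW_CELLULARITY` but still called.

## Purity and the detectability bound

The observable imbalance is diluted by non-tumor cells. With effective
purity $\rho$ (purity × subclonal fraction), allele-copy counting gives
the expected VAF:

| event | deletion | copy-neutral LOH |
|---|---|---|
| balance | $1/2$ | $1/2$ |
| loss of WT | $1/(2-\rho)$ | $(1+\rho)/2$ |
| loss of variant | $(1-\rho)/(2-\rho)$ | $(1-\rho)/2$ |

Under the 0.10 threshold, WT loss by deletion is detectable only for
$\rho > 1/3$; copy-neutral LOH for $\rho > 0.2$. The deletion model is the
package default because it is the conservative choice (smaller expected
imbalance at a given purity) and because it explains the observed
false-negative: the one balanced tumor in the worked family had 30%
cellularity, right below the deletion bound
(`expected_vaf("LOSS_WT", 0.30)` = `r round(expected_vaf("LOSS_WT", 0.30), 3)`,
a delta of only 0.088). Which copy-number state the real events had is not
known; both models are provided and none is asserted as truth.

## The binomial evidence model

For a variant observed in $n$ independent tumors, the count $k$ of
loss-of-WT calls is modeled as $X \sim B(n, p)$ with $p$ the
class-conditional per-tumor WT-loss rate. Two scenario tails are
computed exactly (direct pmf summation, no normal approximation — $n$ is
small by construction):

* $P(X \ge k \mid p_\text{benign})$ — small values argue against
  neutrality;
* $P(X \le k \mid p_\text{pathogenic})$ — small values argue against
  pathogenicity.

Default rates come from the reference cohort: $p_\text{benign} = 6/27$
(combined tissues; breast-only $5/26$ is used where the strict decision
example requires it, because the "below 0.05%" property of five-of-five
holds at $5/26$ but not at $6/27$) and $p_\text{pathogenic} = 36/55$.
`decision_table()` tabulates, for each $n$, the smallest $k$ whose
benign tail clears the accepted risk (`alpha_benign`, default 0.05;
strict 0.0005 for a class-2-grade exclusion of neutrality) and the largest
$k$ whose pathogenic tail clears `alpha_pathogenic` (default 0.01) for
excluding pathogenicity. At the strict risk, no series shorter than five
tumors can ever decide, and five requires five-of-five — the basis for the
"at least five samples" guidance.

`classify_by_loh()` grades the evidence (strong below 0.05%, moderate
below 1%, exclude-pathogenicity below 1% on the other tail, else
inconclusive). The moderate boundary at 1% is interpretive — it mirrors
the "probability for a benign variant close to 1%" zone in which the
recurrent three-of-three and four-of-five patterns fall under the
breast-only benign rate. This grade is deliberately *not* a statistical
test and never a definitive class: it is an ad hoc prioritization
heuristic for deciding whether collecting more tumors or other evidence is
worthwhile. Independence of tumors from the same patient or family is
assumed, as the binomial model requires; related tumors violate it and
overstate the evidence.

One published claim is not reproducible and is not asserted anywhere: the
probability for a pathogenic variant to present one-of-five LOH evaluates
to about 5% at $p = 36/55$, not below 1%; the rate behind that sentence is
unknown.

## Multifactorial combination

Component likelihood ratios (co-segregation, tumor pathology, family
history, co-occurrence) are inputs — their internal computation is by
external models on pedigree and consortium data and is out of scope.
`combine_odds()` multiplies them in log space (co-segregation LRs can be
enormous; the product is accurate up to the double-precision limit near
1e308), and the posterior is computed on the logit scale:
$\operatorname{logit}(P_\text{post}) = \operatorname{logit}(P_\text{prior}) + \log(\text{odds})$.
The default prior is 0.03, the value used for the worked variants; priors
are variant-specific in the wider literature and the argument is always
explicit.

Tier bands follow the 5-tier posterior classification: above 0.99 tier 5,
0.95–0.99 tier 4, 0.05–0.949 tier 3, 0.001–0.049 tier 2, below 0.001
tier 1. The published bands leave the gaps 0.949–0.95 and 0.049–0.05
unassigned; the implementation closes each gap downward (a posterior of
0.9495 is tier 3), and each listed edge belongs to the band that lists it
(0.99 is tier 4, 0.95 tier 4, 0.05 tier 3, 0.001 tier 2). An LOH-evidence
term may be multiplied in as one more LR (`loh_lr`), but no validated
weighting exists yet, so it is off by default and labelled experimental.

One row of the packaged multifactorial table (c.5497G>A) is internally
inconsistent in its source: the published odds match neither the product
of its published LRs nor the odds implied by its published posterior. The
row ships for completeness; numerical checks use only the consistent
c.4963T>C row.

## The synthetic-data generator

`simulate_cohort()` emulates the structure the analysis assumes: carriers
of class-labelled variants whose tumors draw a latent second-hit event
(`LOSS_WT` with class-conditional probability, `LOSS_VARIANT`, else
balance), a uniform purity, and an observation through one of the two
measurement paths — binomial read counts at a configured depth, or
Gaussian pyrosequencing replicates clipped to \[0, 1\] (clipping bias is
negligible at the default sd of 0.02 away from the boundaries). Default
conditions mirror the reference cohort: WT-loss rates 0.654/0.222 and
variant-loss rates 0.055/0.148 for pathogenic/benign, purity 0.30–0.90
(the cellularity range of the worked family), triplicate pyrosequencing
with sd 0.02, NGS depth 1000, deletion copy model, fully clonal events.
All draws flow from one integer seed, consumed variant by variant and
sample by sample (event, purity, subclonal fraction, then measurement
noise), so cohorts are bit-reproducible.

What the generator does *not* model — and therefore what passing tests on
synthetic data cannot show about real tumors: FFPE artifacts and DNA
quality, mapping and GC bias, intratumor heterogeneity beyond a single
multiplicative subclonal factor, correlated tumors from one family,
pathologist error in cellularity estimates, and any genomic context
(coordinates, flanking markers, multi-SNP haplotypes).

## Numerical and design choices

* Binomial pmf via `lchoose` + `log1p` accumulation, exact to 1e-12
  normalization for $n \le 10^3$ and stable to $n = 10^4$;
  cross-checked in tests against both exhaustive $2^n$ enumeration
  ($n \le 12$) and the stats distribution functions — two independent
  routes kept deliberately separate from the implementation.
* Percentages are kept at full precision; the printed-style rendering
  rounds half away from zero to integers (`render_pct()`). The
  one-decimal value 65.4% arises from 36/55 = 65.45% by truncation;
  both renderings are exposed rather than hidden.
* The per-variant count table for the reference cohort is the package's
  ground truth; two of its source rows print percentages inconsistent
  with their own counts (the largest breast series and one single-sample
  row), and the counts — which conserve exactly across all totals — are
  what the package encodes.
* The effect-stratified contrast (missense vs truncating WT-loss rates)
  exposes its grouping as a parameter: several poolings of the published
  per-variant counts are compatible with the reported 74%-vs-52%
  contrast, so no single grouping is asserted. The default pools all
  non-missense effects; on the packaged counts it gives 73% vs 55%, the
  same direction and, as reported, not statistically significant.
* Sample tables are tab-separated with `#` comments; VAF-like columns
  larger than 1 (and at most 100) are read as percentages and divided by
  100, with a message — the convention in which tumor VAFs are usually
  printed.
* The analysis workflow ships as numbered scripts under `analysis/`
  (cohort summary, family calls, decision design, multifactorial
  classification, simulation validation) over the package functions; the
  scripts are the command-line surface, and every computation they
  perform is a tested package function.

## Problem sizes

Simulation-backed checks use cohorts of 500–1,000 samples per condition
(e.g. parameter recovery at 500 pathogenic samples, purity sweeps at 250
samples per purity point, 200 null replicates for the type-I error check)
— large enough that binomial sampling error is well inside the asserted
tolerances (±0.05 for rate recovery at $n = 500$; three standard errors
for generative-rate checks), and small enough to run in seconds.

## Known limitations

* Purity is an input, never estimated from data; a wrong cellularity
  estimate propagates directly into the detectability reasoning.
* The binomial framework treats calls as error-free draws; measurement
  false negatives at low purity bias $k$ downward and the evidence toward
  neutrality.
* The benign/pathogenic rates are point estimates from a modest cohort
  (27/55 tumors); no uncertainty in $p$ is propagated into the tails.
* Tier assignment takes the posterior at face value; it inherits whatever
  biases the input LRs carry.
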