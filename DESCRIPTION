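Package: brca1loh
Title: Loss-of-Heterozygosity Evidence for BRCA1 Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for using tumor loss-of-heterozygosity (LOH) patterns as
    evidence in germline BRCA1 variant classification. Calls allelic status
    (balance, loss of the wild-type allele, loss of the variant allele) from
    tumor variant-allele fractions measured by pyrosequencing replicates or
    sequencing read depths, summarizes LOH patterns per variant and per
    classification class, evaluates binomial-model evidence for excluding
    neutrality or pathogenicity from repeated LOH observations, and combines
    component likelihood ratios with a prior into a posterior probability of
    pathogenicity with a 5-tier class assignment. Includes a synthetic
    carrier-cohort simulator with a latent second-hit event structure and a
    packaged reference cohort of published per-variant LOH counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    GenomicRanges,
    jsonlite,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
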