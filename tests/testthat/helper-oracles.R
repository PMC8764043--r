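# Independent oracles and small builders shared across tests.

# Brute-force binomial tail: enumerate all 2^n outcome sequences, weight
# each by p^k (1-p)^(n-k), and sum those with at least / at most k losses.
brute_tail <- function(k, n, p, side = c("ge", "le")) {
  side <- match.arg(side)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  s <- rowSums(outcomes)
  w <- p^s * (1 - p)^(n - s)
  if (side == "ge") sum(w[s >= k]) else sum(w[s <= k])
}

# Textbook pooled-variance two-sample t statistic and two-sided p-value.
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Closed-form 2x2 chi-squared (no continuity correction):
# N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# One PYRO sample row for caller tests.
pyro_sample <- function(vafs, sample_id = "S1", variant_id = "v1",
                        cellularity = NA_real_, germline_vaf = 0.5,
                        tissue = "BREAST") {
  tibble::tibble(
    sample_id = sample_id, variant_id = variant_id, tissue = tissue,
    cellularity = cellularity, method = "PYRO",
    replicate_vafs = list(vafs),
    alt_depth = NA_integer_, total_depth = NA_integer_,
    germline_vaf = germline_vaf, truth_event = NA_character_
  )
}

ngs_sample <- function(alt, total, sample_id = "S1", variant_id = "v1",
                       cellularity = NA_real_, germline_vaf = 0.5,
                       tissue = "BREAST") {
  tibble::tibble(
    sample_id = sample_id, variant_id = variant_id, tissue = tissue,
    cellularity = cellularity, method = "NGS",
    replicate_vafs = list(NULL),
    alt_depth = as.integer(alt), total_depth = as.integer(total),
    germline_vaf = germline_vaf, truth_event = NA_character_
  )
}

# Minimal VCF with AD depths: one biallelic and one multi-allelic record.
write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr17,length=83257441>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR1",
    "chr17\t43063903\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:12,88",
    "chr17\t43064000\t.\tC\tA,T\t.\tPASS\t.\tGT:AD\t1/2:10,30,60"
  ), path)
  path
}

# Minimal VCF whose genotypes lack allelic depths.
write_test_vcf_no_ad <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr17,length=83257441>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR1",
    "chr17\t43063903\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"
  ), path)
  path
}
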