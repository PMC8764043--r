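# Allelic-status calling from tumor allele fractions: the >10% imbalance
# rule, replicate aggregation, and the replicate t-test against a control.

new_call <- function(sample_id, tumor_vaf, reference_vaf, threshold,
                     qc_flags = "") {
  delta <- tumor_vaf - reference_vaf
  status <- dplyr::case_when(
    delta > threshold ~ "LOSS_WT",
    delta < -threshold ~ "LOSS_VARIANT",
    TRUE ~ "BALANCE"
  )
  tibble(
    sample_id = sample_id,
    status = status,
    tumor_vaf = tumor_vaf,
    reference_vaf = reference_vaf,
    delta = delta,
    qc_flags = qc_flags
  )
}

#' Aggregate replicate VAF measurements
#'
#' @param replicate_vafs Numeric vector of replicate allele fractions
#'   (length >= 1).
#' @return List with `mean` and `sd` (sample standard deviation; 0 for a
#'   single replicate).
#' @examples
#' aggregate_replicates(c(0.60, 0.65, 0.70))
#' @export
aggregate_replicates <- function(replicate_vafs) {
  if (length(replicate_vafs) == 0 || all(is.na(replicate_vafs))) {
    abort("at least one replicate VAF is required")
  }
  replicate_vafs <- replicate_vafs[!is.na(replicate_vafs)]
  check_fraction(replicate_vafs, "replicate_vafs")
  s <- if (length(replicate_vafs) > 1) stats::sd(replicate_vafs) else 0
  list(mean = mean(replicate_vafs), sd = s)
}

#' Two-sample t-test between tumor and control replicates
#'
#' Student's two-sample t-test (equal variances) comparing the tumor
#' replicate VAFs against replicates from a non-carrier control. Reported
#' as QC metadata alongside the threshold rule; it never decides the call.
#'
#' @param sample_vafs,control_vafs Numeric vectors of replicate allele
#'   fractions, each of length >= 2.
#' @return Tibble with `mean_vaf`, `sd_vaf`, `t_statistic`, `p_value`,
#'   `n_sample`, `n_control`.
#' @export
replicate_t_test <- function(sample_vafs, control_vafs) {
  if (length(sample_vafs) < 2 || length(control_vafs) < 2) {
    abort("the replicate t-test needs >= 2 replicates in each group")
  }
  check_fraction(sample_vafs, "sample_vafs")
  check_fraction(control_vafs, "control_vafs")
  if (stats::sd(sample_vafs) == 0 && stats::sd(control_vafs) == 0) {
    # degenerate: no within-group variance; identical means => no evidence
    t_stat <- if (mean(sample_vafs) == mean(control_vafs)) 0 else Inf
    p_val <- if (t_stat == 0) 1 else 0
  } else {
    ht <- stats::t.test(sample_vafs, control_vafs, var.equal = TRUE)
    t_stat <- unname(ht$statistic)
    p_val <- ht$p.value
  }
  tibble(
    mean_vaf = mean(sample_vafs),
    sd_vaf = stats::sd(sample_vafs),
    t_statistic = t_stat,
    p_value = p_val,
    n_sample = length(sample_vafs),
    n_control = length(control_vafs)
  )
}

#' Call allelic status from an aggregated tumor VAF
#'
#' Applies the imbalance rule: loss of the wild-type allele when the tumor
#' VAF exceeds the reference by strictly more than `threshold` (variant
#' allele enriched), loss of the variant allele when it falls below the
#' reference by strictly more than `threshold`, allelic balance otherwise.
#' A delta of exactly `threshold` is balance ("superior to" is strict).
#'
#' @param tumor_vaf Aggregated tumor VAF in \[0, 1\]. Vectorized.
#' @param reference_vaf Germline/reference VAF in \[0, 1\] (heterozygous
#'   expectation 0.5).
#' @param threshold Imbalance threshold in (0, 0.5); default 0.10.
#' @param sample_id Optional identifier(s) carried onto the call.
#' @return Tibble with one row per call: `sample_id`, `status`,
#'   `tumor_vaf`, `reference_vaf`, `delta`, `qc_flags`.
#' @examples
#' call_allelic_status(c(0.65, 0.49), 0.5)
#' @export
call_allelic_status <- function(tumor_vaf, reference_vaf = 0.5,
                                threshold = 0.10, sample_id = NA_character_) {
  check_fraction(tumor_vaf, "tumor_vaf")
  check_fraction(reference_vaf, "reference_vaf")
  if (any(threshold <= 0 | threshold >= 0.5)) {
    abort("threshold must lie in (0, 0.5)")
  }
  new_call(sample_id, tumor_vaf, reference_vaf, threshold)
}

#' Call allelic status from read depths
#'
#' @param alt_depth,total_depth Variant-supporting and total read counts;
#'   `alt_depth <= total_depth`, `total_depth > 0`.
#' @param reference_vaf,threshold As in [call_allelic_status()].
#' @param min_depth Total depth below which the call is flagged
#'   `LOW_DEPTH` (flagged, not suppressed).
#' @param sample_id Optional identifier(s).
#' @return Call tibble as in [call_allelic_status()].
#' @export
call_from_reads <- function(alt_depth, total_depth, reference_vaf = 0.5,
                            threshold = 0.10, min_depth = 50,
                            sample_id = NA_character_) {
  if (any(total_depth <= 0)) abort("total_depth must be positive")
  if (any(alt_depth > total_depth | alt_depth < 0)) {
    abort("need 0 <= alt_depth <= total_depth")
  }
  out <- call_allelic_status(alt_depth / total_depth, reference_vaf,
                             threshold, sample_id)
  out$qc_flags <- ifelse(total_depth < min_depth, "LOW_DEPTH", "")
  out
}

#' Call allelic status for every sample in a cohort
#'
#' Routes pyrosequencing samples through replicate aggregation and NGS
#' samples through the read-depth path. The reference VAF is the sample's
#' `germline_vaf` when present, else 0.5 with a `NO_GERMLINE_REFERENCE`
#' flag; samples with cellularity below `low_cellularity_cutoff` are
#' flagged `LOW_CELLULARITY` (a call is still made — low purity dilutes
#' imbalance toward balance, so such calls are less trustworthy).
#'
#' @param cohort A [variant_cohort()] (or its samples tibble).
#' @param threshold Imbalance threshold, default 0.10.
#' @param min_depth NGS depth QC cutoff, default 50.
#' @param low_cellularity_cutoff Cellularity QC cutoff, default 0.30.
#' @return Tibble of calls, one row per sample, carrying `variant_id` and
#'   `tissue` alongside the call columns; `qc_flags` is a
#'   semicolon-separated string (empty when clean).
#' @export
call_cohort <- function(cohort, threshold = 0.10, min_depth = 50,
                        low_cellularity_cutoff = 0.30) {
  samples <- if (inherits(cohort, "variant_cohort")) cohort$samples else cohort
  n <- nrow(samples)
  ref <- if ("germline_vaf" %in% names(samples)) samples$germline_vaf
         else rep(NA_real_, n)
  no_ref <- is.na(ref)
  ref[no_ref] <- 0.5
  is_pyro <- samples$method == "PYRO"
  vaf <- numeric(n)
  if (any(is_pyro)) {
    vaf[is_pyro] <- vapply(samples$replicate_vafs[is_pyro],
                           function(v) aggregate_replicates(v)$mean,
                           numeric(1))
  }
  if (any(!is_pyro)) {
    if (any(samples$total_depth[!is_pyro] <= 0)) {
      abort("total_depth must be positive")
    }
    vaf[!is_pyro] <- samples$alt_depth[!is_pyro] / samples$total_depth[!is_pyro]
  }
  out <- call_allelic_status(vaf, ref, threshold, samples$sample_id)
  low_depth <- !is_pyro & samples$total_depth < min_depth
  low_cell <- if ("cellularity" %in% names(samples)) {
    !is.na(samples$cellularity) & samples$cellularity < low_cellularity_cutoff
  } else {
    rep(FALSE, n)
  }
  out$qc_flags <- vapply(seq_len(n), function(i) {
    flags <- c(if (low_cell[i]) "LOW_CELLULARITY",
               if (low_depth[i]) "LOW_DEPTH",
               if (no_ref[i]) "NO_GERMLINE_REFERENCE")
    paste(flags, collapse = ";")
  }, character(1))
  out$variant_id <- samples$variant_id
  out$tissue <- if ("tissue" %in% names(samples)) samples$tissue
                else NA_character_
  out
}

#' Call allelic status for one tumor sample record
#'
#' @param sample One-row samples tibble (see [variant_cohort()]).
#' @inheritParams call_cohort
#' @return One-row call tibble with `variant_id` and `tissue` attached.
#' @export
call_sample <- function(sample, threshold = 0.10, min_depth = 50,
                        low_cellularity_cutoff = 0.30) {
  flags <- character(0)
  ref <- 0.5
  if ("germline_vaf" %in% names(sample) && !is.na(sample$germline_vaf)) {
    ref <- sample$germline_vaf
  } else {
    flags <- c(flags, "NO_GERMLINE_REFERENCE")
  }
  if (sample$method == "PYRO") {
    agg <- aggregate_replicates(sample$replicate_vafs[[1]])
    out <- call_allelic_status(agg$mean, ref, threshold, sample$sample_id)
  } else {
    out <- call_from_reads(sample$alt_depth, sample$total_depth, ref,
                           threshold, min_depth, sample$sample_id)
    if (nzchar(out$qc_flags)) flags <- c(flags, out$qc_flags)
  }
  if ("cellularity" %in% names(sample) && !is.na(sample$cellularity) &&
      sample$cellularity < low_cellularity_cutoff) {
    flags <- c(flags, "LOW_CELLULARITY")
  }
  out$qc_flags <- paste(sort(unique(flags)), collapse = ";")
  out$variant_id <- sample$variant_id
  out$tissue <- if ("tissue" %in% names(sample)) sample$tissue else NA_character_
  out
}
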