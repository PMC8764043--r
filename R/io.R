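# Readers/writers for the sample-table format and VCF allele-depth
# extraction. The sample table is tab-separated with one header row;
# '#' lines are comments. VAF-like columns printed as percentages
# (values in (1, 100]) are converted to fractions with a message.

SAMPLE_REQUIRED_COLS <- c("sample_id", "variant_id", "variant_class",
                          "effect", "tissue", "method")

percent_to_fraction <- function(x, col) {
  pct <- !is.na(x) & x > 1 & x <= 100
  if (any(pct)) {
    message(sprintf("column %s: %d value(s) > 1 interpreted as percent and divided by 100",
                    col, sum(pct)))
    x[pct] <- x[pct] / 100
  }
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort(sprintf("column %s: values outside [0, 1] after percent conversion", col))
  }
  x
}

#' Read a tumor sample table
#'
#' Reads the tab-separated sample format into a [variant_cohort()].
#' Required columns: `sample_id`, `variant_id`, `variant_class`, `effect`,
#' `tissue`, `method`. Pyrosequencing rows carry replicate columns
#' `rep1..repN`; NGS rows carry integer `alt_depth`, `total_depth`.
#' Optional: `cellularity`, `germline_vaf`, `truth_event`. Fraction
#' columns given as percentages are converted (with a message).
#'
#' @param path Path to a TSV file (`#` lines are comments).
#' @return A [variant_cohort()].
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (nrow(df) == 0) abort(sprintf("%s: no data rows", path))
  missing_cols <- setdiff(SAMPLE_REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  has_depth <- all(c("alt_depth", "total_depth") %in% names(df))
  if (any(df$method == "PYRO") && !length(rep_cols)) {
    abort(sprintf("%s: PYRO rows need rep1..repN columns", path))
  }
  if (any(df$method == "NGS") && !has_depth) {
    abort(sprintf("%s: NGS rows need alt_depth and total_depth columns", path))
  }
  for (col in c(rep_cols, intersect("germline_vaf", names(df)))) {
    df[[col]] <- percent_to_fraction(df[[col]], col)
  }
  if ("cellularity" %in% names(df)) {
    df$cellularity <- percent_to_fraction(df$cellularity, "cellularity")
  }
  reps <- if (length(rep_cols)) {
    rep_mat <- as.matrix(df[rep_cols])
    lapply(seq_len(nrow(df)), function(i) {
      v <- unname(rep_mat[i, ])
      v <- v[!is.na(v)]
      if (length(v)) v else NULL
    })
  } else {
    vector("list", nrow(df))
  }
  samples <- tibble(
    sample_id = as.character(df$sample_id),
    variant_id = as.character(df$variant_id),
    tissue = as.character(df$tissue),
    cellularity = if ("cellularity" %in% names(df)) df$cellularity else NA_real_,
    method = as.character(df$method),
    replicate_vafs = reps,
    alt_depth = if (has_depth) as.integer(df$alt_depth) else NA_integer_,
    total_depth = if (has_depth) as.integer(df$total_depth) else NA_integer_,
    germline_vaf = if ("germline_vaf" %in% names(df)) df$germline_vaf else NA_real_,
    truth_event = if ("truth_event" %in% names(df))
      as.character(df$truth_event) else NA_character_
  )
  samples$alt_depth[samples$method != "NGS"] <- NA_integer_
  samples$total_depth[samples$method != "NGS"] <- NA_integer_
  variants <- df |>
    dplyr::distinct(.data$variant_id, .data$variant_class, .data$effect) |>
    dplyr::rename(classification = "variant_class") |>
    dplyr::mutate(variant_id = as.character(.data$variant_id))
  if (anyDuplicated(variants$variant_id)) {
    abort(sprintf("%s: inconsistent class/effect annotation within a variant", path))
  }
  variant_cohort(variants, samples)
}

#' Write a cohort as a tumor sample table
#'
#' Inverse of [read_sample_table()]; replicate VAFs are written as wide
#' `rep1..repN` columns.
#'
#' @param cohort A [variant_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "variant_cohort"))
  samples <- cohort$samples
  ann <- cohort$variants |>
    dplyr::select("variant_id", variant_class = "classification", "effect")
  df <- dplyr::left_join(samples, ann, by = "variant_id")
  n_rep <- max(c(0L, lengths(df$replicate_vafs)))
  for (j in seq_len(n_rep)) {
    df[[sprintf("rep%d", j)]] <- vapply(df$replicate_vafs, function(v) {
      if (length(v) >= j) v[j] else NA_real_
    }, numeric(1))
  }
  df$replicate_vafs <- NULL
  front <- c("sample_id", "variant_id", "variant_class", "effect",
             "tissue", "method")
  df <- df[c(front, setdiff(names(df), front))]
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Extract allele depths for a variant from a VCF file
#'
#' Reads per-sample allelic depths (the `AD` FORMAT field) for one
#' genotyped variant record and returns the requested alternate's depth
#' and the total depth across alleles. Requires the `VariantAnnotation`
#' package.
#'
#' @param path VCF file path.
#' @param sample_name Genotyped sample to extract.
#' @param chrom,pos Variant locus.
#' @param alt Alternate allele sequence; for multi-allelic records the
#'   matching alternate is resolved.
#' @return List with `alt_depth` and `total_depth`.
#' @export
extract_vaf_from_vcf <- function(path, sample_name, chrom, pos, alt) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("extract_vaf_from_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  hit <- which(as.character(GenomicRanges::seqnames(rr)) == chrom &
                 BiocGenerics::start(rr) == pos)
  if (!length(hit)) {
    abort(sprintf("no record at %s:%d in %s", chrom, pos, path))
  }
  hit <- hit[1]
  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno)) {
    abort(sprintf("%s: no AD (allelic depths) FORMAT field", path))
  }
  if (!sample_name %in% colnames(geno$AD)) {
    abort(sprintf("%s: sample %s not present", path, sample_name))
  }
  ad <- geno$AD[hit, sample_name][[1]]
  if (is.null(ad) || all(is.na(ad))) {
    abort(sprintf("%s: allelic depths missing for %s at %s:%d",
                  path, sample_name, chrom, pos))
  }
  alts <- as.character(rr$ALT[[hit]])
  j <- match(alt, alts)
  if (is.na(j)) {
    abort(sprintf("alternate %s not present at %s:%d (has: %s)",
                  alt, chrom, pos, paste(alts, collapse = ",")))
  }
  list(alt_depth = as.integer(ad[j + 1]), total_depth = as.integer(sum(ad)))
}
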