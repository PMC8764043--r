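# Packaged reference data: the published per-variant LOH call counts for
# the 97-tumor carrier cohort, the five worked family-1 tumors with their
# VAFs and cellularities, and the multifactorial inputs for the two
# recurrently-sampled VUS.

brca1loh_extdata <- function(file) {
  path <- system.file("extdata", file, package = "brca1loh")
  if (path == "") abort(sprintf("packaged data file not found: %s", file))
  path
}

#' Load the packaged reference cohort data
#'
#' Returns the published summary-level data shipped with the package:
#' \describe{
#'   \item{counts}{Per-variant, per-tissue counts of allelic balance /
#'     loss of variant allele / loss of WT allele calls for the 97-tumor
#'     cohort (26 germline variants; 90 breast, 7 ovarian tumors).}
#'   \item{family1}{The five tumors of the family segregating c.4963T>C:
#'     tumor VAFs with pathologist-estimated cellularity, as a samples
#'     table ready for [call_cohort()].}
#'   \item{multifactorial}{Prior and component likelihood ratios for the
#'     two recurrently-sampled VUS, with the published odds/posterior for
#'     reference.}
#' }
#'
#' @return Named list of tibbles `counts`, `family1`, `multifactorial`.
#' @examples
#' ref <- load_reference_cohort()
#' sum(ref$counts$n_balance + ref$counts$n_loss_variant + ref$counts$n_loss_wt)
#' @export
load_reference_cohort <- function() {
  counts <- readr::read_tsv(brca1loh_extdata("loh_counts.tsv"),
                            comment = "#", show_col_types = FALSE)
  fam <- readr::read_tsv(brca1loh_extdata("family1_samples.tsv"),
                         comment = "#", show_col_types = FALSE)
  fam$replicate_vafs <- vector("list", nrow(fam))
  mfl <- readr::read_tsv(brca1loh_extdata("multifactorial_table.tsv"),
                         comment = "#", show_col_types = FALSE)
  list(counts = counts, family1 = fam, multifactorial = mfl)
}

#' Variants table of the reference cohort
#'
#' @param counts Counts tibble from [load_reference_cohort()].
#' @return Tibble with one row per distinct variant (`variant_id`,
#'   `hgvs_p`, `classification`, `effect`).
#' @export
reference_variants <- function(counts = load_reference_cohort()$counts) {
  dplyr::distinct(counts, .data$variant_id, .data$hgvs_p,
                  .data$classification, .data$effect)
}

#' Expand reference counts into per-sample allelic-status calls
#'
#' The published counts are sufficient statistics for every summary in
#' this package; this helper expands them into one synthetic call row per
#' tumor (sample ids are generated) so that the call-level summary
#' operations can be applied to the reference cohort.
#'
#' @param counts Counts tibble from [load_reference_cohort()].
#' @return Call-shaped tibble with `sample_id`, `variant_id`, `tissue`,
#'   `status`.
#' @export
counts_to_calls <- function(counts = load_reference_cohort()$counts) {
  purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    status <- rep(c("BALANCE", "LOSS_VARIANT", "LOSS_WT"),
                  times = c(row$n_balance, row$n_loss_variant, row$n_loss_wt))
    if (!length(status)) return(NULL)
    tibble(
      sample_id = sprintf("%s_%s_%02d", row$variant_id,
                          tolower(row$tissue), seq_along(status)),
      variant_id = row$variant_id,
      tissue = row$tissue,
      status = status
    )
  })
}
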