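#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

VARIANT_CLASSES <- c("PATHOGENIC", "LIKELY_PATHOGENIC", "VUS",
                     "LIKELY_BENIGN", "BENIGN")
VARIANT_EFFECTS <- c("MISSENSE", "NONSENSE", "FRAMESHIFT", "SYNONYMOUS",
                     "SPLICE", "DUPLICATION")
TISSUES        <- c("BREAST", "OVARY")
METHODS        <- c("PYRO", "NGS")
EVENTS         <- c("BALANCE", "LOSS_WT", "LOSS_VARIANT")
COPY_MODELS    <- c("DELETION", "CN_LOH")

#' Construct a variant cohort
#'
#' A cohort bundles a table of germline variants with a table of tumor
#' samples from carriers of those variants. Every sample must point to a
#' known variant; each sample carries either pyrosequencing replicate VAFs
#' (`replicate_vafs`, a list-column of numeric vectors) or sequencing read
#' depths (`alt_depth`, `total_depth`), never both.
#'
#' @param variants Tibble with columns `variant_id`, `classification`
#'   (one of `r paste(VARIANT_CLASSES, collapse = ", ")`), `effect`
#'   (one of `r paste(VARIANT_EFFECTS, collapse = ", ")`), and optionally
#'   `hgvs_c`, `hgvs_p`.
#' @param samples Tibble with columns `sample_id`, `variant_id`, `tissue`,
#'   `method`, and the method-conditional measurement columns; optional
#'   `cellularity`, `germline_vaf`, `truth_event`.
#' @return An object of class `variant_cohort` (a list with elements
#'   `variants` and `samples`).
#' @export
variant_cohort <- function(variants, samples) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (!all(c("variant_id", "classification", "effect") %in% names(variants))) {
    abort("`variants` needs columns variant_id, classification, effect")
  }
  if (anyDuplicated(variants$variant_id)) {
    abort("variant_id must be unique within a cohort")
  }
  bad_class <- setdiff(unique(variants$classification), VARIANT_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown classification: ", paste(bad_class, collapse = ", ")))
  }
  bad_eff <- setdiff(unique(variants$effect), VARIANT_EFFECTS)
  if (length(bad_eff)) {
    abort(paste0("unknown effect: ", paste(bad_eff, collapse = ", ")))
  }
  if (!all(c("sample_id", "variant_id", "tissue", "method") %in% names(samples))) {
    abort("`samples` needs columns sample_id, variant_id, tissue, method")
  }
  orphan <- setdiff(samples$variant_id, variants$variant_id)
  if (length(orphan)) {
    abort(paste0("samples reference unknown variants: ",
                 paste(orphan, collapse = ", ")))
  }
  bad_tissue <- setdiff(unique(samples$tissue), TISSUES)
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue: ", paste(bad_tissue, collapse = ", ")))
  }
  bad_method <- setdiff(unique(samples$method), METHODS)
  if (length(bad_method)) {
    abort(paste0("unknown method: ", paste(bad_method, collapse = ", ")))
  }
  validate_sample_measurements(samples)
  structure(list(variants = variants, samples = samples),
            class = "variant_cohort")
}

validate_sample_measurements <- function(samples) {
  has_pyro <- if ("replicate_vafs" %in% names(samples)) {
    vapply(samples$replicate_vafs,
           function(v) length(v) > 0 && !all(is.na(v)), logical(1))
  } else {
    rep(FALSE, nrow(samples))
  }
  has_ngs <- if (all(c("alt_depth", "total_depth") %in% names(samples))) {
    !is.na(samples$alt_depth) & !is.na(samples$total_depth)
  } else {
    rep(FALSE, nrow(samples))
  }
  bad <- which(has_pyro == has_ngs)
  if (length(bad)) {
    abort(sprintf(
      "sample row %d (%s): exactly one of replicate_vafs or alt/total depth must be present",
      bad[1], samples$sample_id[bad[1]]))
  }
  if (any(has_pyro)) {
    all_ok <- vapply(samples$replicate_vafs[has_pyro],
                     function(v) !any(v < 0 | v > 1, na.rm = TRUE), logical(1))
    if (!all(all_ok)) {
      bad <- which(has_pyro)[!all_ok][1]
      abort(sprintf("sample row %d (%s): replicate VAFs outside [0,1]",
                    bad, samples$sample_id[bad]))
    }
  }
  if (any(has_ngs)) {
    ok <- samples$alt_depth[has_ngs] >= 0 &
      samples$alt_depth[has_ngs] <= samples$total_depth[has_ngs]
    if (!all(ok)) {
      bad <- which(has_ngs)[!ok][1]
      abort(sprintf("sample row %d (%s): need 0 <= alt_depth <= total_depth",
                    bad, samples$sample_id[bad]))
    }
  }
  invisible(TRUE)
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat(sprintf("<variant_cohort> %d variants, %d tumor samples\n",
              nrow(x$variants), nrow(x$samples)))
  cls <- table(x$variants$classification)
  cat("  variants by class: ",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n", sep = "")
  tis <- table(x$samples$tissue)
  cat("  samples by tissue: ",
      paste(sprintf("%s=%d", names(tis), tis), collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_fraction <- function(x, name, allow_na = FALSE) {
  ok <- is.numeric(x) & (allow_na | !is.na(x))
  if (!all(ok) || any(x < 0 | x > 1, na.rm = TRUE)) {
    abort(sprintf("`%s` must be a fraction in [0, 1]", name))
  }
  invisible(x)
}
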