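# Cohort summaries: per-variant and per-class LOH pattern tables,
# predictor sensitivity/specificity, and the 2x2 class-association test.

#' Render a proportion as an integer percentage
#'
#' Rounds half away from zero (55.5 renders as 56), matching the
#' rendering used throughout the per-variant and class-total tables.
#' Full-precision percentages are always kept alongside.
#'
#' @param x Percentages (0--100 scale); `NA` passes through.
#' @return Integer vector.
#' @export
render_pct <- function(x) {
  out <- ifelse(is.na(x), NA_integer_, as.integer(floor(abs(x) + 0.5) * sign(x)))
  out
}

class_group <- function(classification) {
  dplyr::case_when(
    classification %in% c("PATHOGENIC", "LIKELY_PATHOGENIC") ~ "pathogenic",
    classification %in% c("BENIGN", "LIKELY_BENIGN") ~ "benign",
    TRUE ~ "vus"
  )
}

summary_pcts <- function(df) {
  dplyr::mutate(
    df,
    n_total = .data$n_balance + .data$n_loss_variant + .data$n_loss_wt,
    n_imbalanced = .data$n_loss_variant + .data$n_loss_wt,
    pct_imbalance = ifelse(.data$n_total > 0,
                           100 * .data$n_imbalanced / .data$n_total, NA_real_),
    pct_loss_wt_of_imbalanced = ifelse(.data$n_imbalanced > 0,
                                       100 * .data$n_loss_wt / .data$n_imbalanced,
                                       NA_real_),
    pct_imbalance_render = render_pct(.data$pct_imbalance),
    pct_loss_wt_render = render_pct(.data$pct_loss_wt_of_imbalanced)
  )
}

#' Summarize allelic-status calls per variant
#'
#' One row per germline variant with counts of balance / loss-of-variant /
#' loss-of-WT calls, the percentage of imbalanced (LOH) tumors, and the
#' percentage of imbalanced tumors in which the lost allele was the
#' wild-type one (missing when no tumor is imbalanced). Percentages are
#' kept at full precision with integer renderings alongside.
#'
#' @param calls Call tibble from [call_cohort()] (needs `variant_id`,
#'   `status`, optionally `tissue`).
#' @param variants Variants tibble (needs `variant_id`, `classification`,
#'   `effect`).
#' @param tissue Optional tissue filter (`"BREAST"` or `"OVARY"`).
#' @return Tibble with one row per variant present in `calls` (after any
#'   tissue filter), ordered as in `variants`.
#' @export
summarize_by_variant <- function(calls, variants, tissue = NULL) {
  unknown <- setdiff(unique(calls$variant_id), variants$variant_id)
  if (length(unknown)) {
    abort(paste0("calls reference unknown variants: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, TISSUES)
    calls <- dplyr::filter(calls, .data$tissue == !!tissue)
  }
  counts <- calls |>
    dplyr::count(.data$variant_id, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("BALANCE", "LOSS_VARIANT", "LOSS_WT")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    dplyr::rename(n_balance = "BALANCE", n_loss_variant = "LOSS_VARIANT",
                  n_loss_wt = "LOSS_WT")
  out <- variants |>
    dplyr::select("variant_id", "classification", "effect") |>
    dplyr::inner_join(counts, by = "variant_id") |>
    summary_pcts()
  dplyr::select(out, "variant_id", "classification", "effect",
                "n_balance", "n_loss_variant", "n_loss_wt", "n_total",
                "pct_imbalance", "pct_loss_wt_of_imbalanced",
                "pct_imbalance_render", "pct_loss_wt_render")
}

#' Summarize per-variant rows into class-group totals
#'
#' Pools variants into pathogenic (P/LP), benign (B/LB) and VUS groups,
#' sums counts and recomputes the two percentages from the pooled counts.
#'
#' @param rows Per-variant rows from [summarize_by_variant()].
#' @return One row per class group present in `rows`.
#' @export
summarize_by_class <- function(rows) {
  if (nrow(rows) == 0) abort("no rows to summarize")
  rows |>
    dplyr::mutate(class_group = class_group(.data$classification)) |>
    dplyr::group_by(.data$class_group) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_balance = sum(.data$n_balance),
      n_loss_variant = sum(.data$n_loss_variant),
      n_loss_wt = sum(.data$n_loss_wt),
      .groups = "drop"
    ) |>
    summary_pcts()
}

#' Sensitivity and specificity of loss-of-WT as a pathogenicity predictor
#'
#' Treats each tumor sample as one trial and a loss-of-wild-type call as a
#' positive prediction of pathogenicity. Pathogenic-group samples (P/LP)
#' with loss of WT are true positives; benign-group samples (B/LB) with
#' loss of WT are false positives. VUS samples are excluded.
#'
#' @param calls Call tibble with `variant_id` and `status`.
#' @param variants Variants tibble with `variant_id` and `classification`.
#' @param tissue Optional tissue filter; default pools breast and ovary.
#' @return One-row tibble: `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity` (percentages at full precision) and their integer
#'   renderings.
#' @export
predictor_performance <- function(calls, variants, tissue = NULL) {
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, TISSUES)
    calls <- dplyr::filter(calls, .data$tissue == !!tissue)
  }
  df <- calls |>
    dplyr::inner_join(dplyr::select(variants, "variant_id", "classification"),
                      by = "variant_id") |>
    dplyr::mutate(class_group = class_group(.data$classification)) |>
    dplyr::filter(.data$class_group != "vus")
  if (any(is.na(df$classification))) abort("missing classification")
  if (!all(c("pathogenic", "benign") %in% df$class_group)) {
    abort("need at least one pathogenic and one benign-group sample")
  }
  pos <- df$status == "LOSS_WT"
  path <- df$class_group == "pathogenic"
  tp <- sum(path & pos); fn <- sum(path & !pos)
  fp <- sum(!path & pos); tn <- sum(!path & !pos)
  tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    sensitivity_render = render_pct(100 * tp / (tp + fn)),
    specificity_render = render_pct(100 * tn / (tn + fp))
  )
}

#' Chi-squared test for class association of loss of the wild-type allele
#'
#' 2x2 chi-squared test comparing loss-of-WT frequency between pathogenic
#' and benign-group samples, without continuity correction by default.
#'
#' @param pathogenic_counts Length-2 vector `(loss_wt, other)` for the
#'   pathogenic group.
#' @param benign_counts Length-2 vector `(loss_wt, other)` for the benign
#'   group.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `chi2` and `p`.
#' @export
class_association_test <- function(pathogenic_counts, benign_counts,
                                   correct = FALSE) {
  tab <- rbind(pathogenic_counts, benign_counts)
  if (any(tab < 0)) abort("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("every margin of the 2x2 table must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Loss-of-WT rates by protein-level effect among pathogenic variants
#'
#' Compares the loss-of-wild-type rate between missense and truncating
#' pathogenic variants. The grouping is exposed because several poolings
#' of the published per-variant counts are compatible with the reported
#' contrast; the default pools all non-missense effects as truncating.
#'
#' @param calls,variants As in [summarize_by_variant()].
#' @param truncating_effects Effects pooled into the truncating group.
#' @param tissue Optional tissue filter.
#' @return List with `by_group` (tibble: group, n_loss_wt, n_total,
#'   pct_loss_wt) and `test` (the 2x2 chi-squared result, `NULL` when a
#'   group is empty).
#' @export
effect_stratified_summary <- function(calls, variants,
                                      truncating_effects = c("NONSENSE",
                                                             "FRAMESHIFT",
                                                             "DUPLICATION",
                                                             "SPLICE"),
                                      tissue = NULL) {
  if (!is.null(tissue)) {
    tissue <- match.arg(tissue, TISSUES)
    calls <- dplyr::filter(calls, .data$tissue == !!tissue)
  }
  df <- calls |>
    dplyr::inner_join(dplyr::select(variants, "variant_id", "classification",
                                    "effect"),
                      by = "variant_id") |>
    dplyr::filter(class_group(.data$classification) == "pathogenic") |>
    dplyr::mutate(group = ifelse(.data$effect %in% truncating_effects,
                                 "truncating", "missense"))
  by_group <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_loss_wt = sum(.data$status == "LOSS_WT"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_loss_wt = ifelse(.data$n_total > 0,
                                       100 * .data$n_loss_wt / .data$n_total,
                                       NA_real_))
  test <- NULL
  if (all(c("missense", "truncating") %in% by_group$group)) {
    m <- by_group[by_group$group == "missense", ]
    t <- by_group[by_group$group == "truncating", ]
    if (m$n_total > 0 && t$n_total > 0 &&
        (m$n_loss_wt + t$n_loss_wt) > 0 &&
        (m$n_total - m$n_loss_wt + t$n_total - t$n_loss_wt) > 0) {
      test <- class_association_test(
        c(t$n_loss_wt, t$n_total - t$n_loss_wt),
        c(m$n_loss_wt, m$n_total - m$n_loss_wt)
      )
    }
  }
  list(by_group = by_group, test = test)
}
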