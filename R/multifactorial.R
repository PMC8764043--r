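# Multifactorial (Bayesian) combination: component likelihood ratios for
# causality multiply into overall odds, which update a prior probability
# of pathogenicity into a posterior mapped to the 5-tier classification.
# Component LRs (co-segregation, tumor pathology, family history,
# co-occurrence) are inputs computed by external models.

#' Combine component likelihood ratios into overall odds for causality
#'
#' Product over the provided components; absent components contribute 1.
#' Accumulated in log space so that very large co-segregation LRs do not
#' overflow intermediates.
#'
#' @param lr_components Named numeric vector or list of positive LRs
#'   (e.g. `cosegregation`, `pathology`, `family_history`,
#'   `cooccurrence`).
#' @return Combined odds (positive scalar); 1 for an empty set.
#' @examples
#' combine_odds(c(cosegregation = 68.44, pathology = 152.88,
#'                family_history = 8.71))
#' @export
combine_odds <- function(lr_components = numeric(0)) {
  lr <- unlist(lr_components)
  if (length(lr) == 0) return(1)
  if (any(!is.finite(lr) | lr <= 0)) {
    abort("all likelihood ratios must be positive and finite")
  }
  exp(sum(log(lr)))
}

#' Posterior probability of pathogenicity
#'
#' Bayes on the odds scale: posterior odds = prior odds x combined LR,
#' computed on the logit scale (`plogis(qlogis(prior) + log(odds))`) so it
#' stays accurate for odds up to and beyond 1e300.
#'
#' @param prior Prior probability of pathogenicity, strictly in (0, 1).
#' @param odds Combined odds for causality (> 0).
#' @return Posterior probability in (0, 1).
#' @examples
#' posterior_probability(0.5, 3)  # 0.75
#' @export
posterior_probability <- function(prior, odds) {
  if (any(prior <= 0 | prior >= 1)) {
    abort("prior must lie strictly in (0, 1)")
  }
  if (any(odds <= 0)) abort("odds must be positive")
  stats::plogis(stats::qlogis(prior) + log(odds))
}

#' Map a posterior probability to the 5-tier class
#'
#' Posterior-probability bands: class 5 (pathogenic) above 0.99, class 4
#' (likely pathogenic) 0.95--0.99, class 3 (uncertain) 0.05--0.949, class
#' 2 (likely benign) 0.001--0.049, class 1 (benign) below 0.001. Band
#' edges: a posterior of exactly 0.99 is class 4, exactly 0.95 class 4,
#' exactly 0.05 class 3, exactly 0.001 class 2 (each edge belongs to the
#' band that lists it as its bound; the published band gaps 0.949--0.95
#' and 0.049--0.05 fall to the lower class).
#'
#' @param posterior Posterior probability in \[0, 1\]. Vectorized.
#' @return Integer tier 1--5.
#' @examples
#' posterior_tier(c(0.99965, 0.5, 0.0005))
#' @export
posterior_tier <- function(posterior) {
  check_fraction(posterior, "posterior")
  dplyr::case_when(
    posterior > 0.99 ~ 5L,
    posterior >= 0.95 ~ 4L,
    posterior >= 0.05 ~ 3L,
    posterior >= 0.001 ~ 2L,
    TRUE ~ 1L
  )
}

#' Multifactorial classification of one variant
#'
#' Combines the prior with the component LRs into odds, posterior, and
#' tier. An LOH-recurrence evidence term may be supplied as an additional
#' LR component (`loh`); weighting LOH into the multifactorial model this
#' way is experimental and off by default.
#'
#' @param variant_id Variant identifier.
#' @param lr_components Named positive LRs; see [combine_odds()].
#' @param prior Prior probability of pathogenicity (default 0.03, the
#'   value used for the worked BRCA1 variants; priors are variant-specific
#'   in the wider literature).
#' @param loh_lr Optional experimental LOH likelihood-ratio component.
#' @return One-row tibble: `variant_id`, `prior`, the LR components (as a
#'   list-column `lr_components`), `combined_odds`, `posterior`, `tier`.
#' @examples
#' classify_variant("c.4963T>C",
#'                  c(cosegregation = 68.44, pathology = 152.88,
#'                    family_history = 8.71))
#' @export
classify_variant <- function(variant_id, lr_components, prior = 0.03,
                             loh_lr = NULL) {
  lr <- unlist(lr_components)
  if (!is.null(loh_lr)) lr <- c(lr, loh = loh_lr)
  odds <- combine_odds(lr)
  post <- posterior_probability(prior, odds)
  tibble(
    variant_id = variant_id,
    prior = prior,
    lr_components = list(lr),
    combined_odds = odds,
    posterior = post,
    tier = posterior_tier(post)
  )
}

#' Classify a table of variants
#'
#' @param lr_table Tibble with `variant_id`, `prior`, and LR columns named
#'   `lr_*` (e.g. `lr_cosegregation`, `lr_pathology`,
#'   `lr_family_history`, `lr_cooccurrence`); `NA` LRs are treated as
#'   absent.
#' @return Row-bound [classify_variant()] results.
#' @export
classify_variants <- function(lr_table) {
  lr_cols <- grep("^lr_", names(lr_table), value = TRUE)
  if (!length(lr_cols)) abort("lr_table needs at least one lr_* column")
  purrr::map_dfr(seq_len(nrow(lr_table)), function(i) {
    row <- lr_table[i, ]
    lr <- unlist(row[lr_cols])
    names(lr) <- sub("^lr_", "", lr_cols)
    lr <- lr[!is.na(lr)]
    classify_variant(row$variant_id, lr, prior = row$prior)
  })
}
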