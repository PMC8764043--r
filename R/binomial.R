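# Binomial evidence framework: the number of tumors with loss of the
# wild-type allele among n independent carriers of the same variant is
# modeled as X ~ B(n, p), with p class-dependent. Tail probabilities under
# the benign and pathogenic rates quantify how surprising an observed LOH
# pattern would be for a neutral or a pathogenic variant.

#' Binomial probability mass
#'
#' P(X = k) for X ~ B(n, p), accumulated in log space
#' (`lchoose` + `log`/`log1p`) so it is stable for n up to at least 1e4.
#'
#' @param k Number of loss-of-WT tumors, `0 <= k <= n`. Vectorized.
#' @param n Number of informative tumors.
#' @param p Per-tumor loss-of-WT probability in \[0, 1\].
#' @return Probability (vector over `k`).
#' @examples
#' binomial_pmf(5, 5, 5 / 26)
#' @export
binomial_pmf <- function(k, n, p) {
  if (any(k < 0 | k > n)) abort("need 0 <= k <= n")
  if (n < 0) abort("n must be non-negative")
  check_fraction(p, "p")
  if (p == 0) return(as.numeric(k == 0))
  if (p == 1) return(as.numeric(k == n))
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

#' Upper binomial tail P(X >= k)
#'
#' Exact direct summation of [binomial_pmf()] over `k..n` (no normal
#' approximation; n is small by construction in this framework).
#'
#' @inheritParams binomial_pmf
#' @return Probability; `tail_ge(0, n, p)` is 1.
#' @export
tail_ge <- function(k, n, p) {
  if (k < 0 || k > n) abort("need 0 <= k <= n")
  sum(binomial_pmf(k:n, n, p))
}

#' Lower binomial tail P(X <= k)
#'
#' @inheritParams binomial_pmf
#' @return Probability; `tail_le(n, n, p)` is 1.
#' @export
tail_le <- function(k, n, p) {
  if (k < 0 || k > n) abort("need 0 <= k <= n")
  sum(binomial_pmf(0:k, n, p))
}

#' Binomial evidence for an observed loss-of-WT pattern
#'
#' Two scenario probabilities for observing `k` loss-of-WT tumors among
#' `n`: the probability of at least `k` under the benign rate (small
#' values argue against neutrality) and of at most `k` under the
#' pathogenic rate (small values argue against pathogenicity).
#'
#' @param k Observed loss-of-WT count.
#' @param n Informative tumors for the variant.
#' @param p_benign Per-tumor loss-of-WT rate for benign variants (default
#'   6/27, the combined-cohort benign rate; breast-only 5/26 also used).
#' @param p_pathogenic Rate for pathogenic variants (default 36/55;
#'   breast-only 32/51).
#' @return One-row tibble: `n`, `k`, `p_benign`, `p_pathogenic`,
#'   `prob_ge_k_given_benign`, `prob_le_k_given_pathogenic`.
#' @examples
#' loh_evidence(5, 5)  # all five tumors lost the WT allele
#' @export
loh_evidence <- function(k, n, p_benign = 6 / 27, p_pathogenic = 36 / 55) {
  tibble(
    n = n, k = k,
    p_benign = p_benign, p_pathogenic = p_pathogenic,
    prob_ge_k_given_benign = tail_ge(k, n, p_benign),
    prob_le_k_given_pathogenic = tail_le(k, n, p_pathogenic)
  )
}

#' Decision thresholds for the binomial framework
#'
#' @param alpha_benign Accepted risk of the observed pattern under
#'   neutrality when excluding neutrality (default 0.05).
#' @param alpha_benign_strict Strict risk for a class-2-grade exclusion of
#'   neutrality (default 0.0005, i.e. 0.05 percent).
#' @param power_pathogenic Desired probability that a truly pathogenic
#'   variant reaches the deciding count (default 0.90).
#' @param alpha_pathogenic Accepted risk under pathogenicity when
#'   excluding pathogenicity (default 0.01).
#' @return List of class `decision_thresholds`.
#' @export
decision_thresholds <- function(alpha_benign = 0.05,
                                alpha_benign_strict = 0.0005,
                                power_pathogenic = 0.90,
                                alpha_pathogenic = 0.01) {
  vals <- c(alpha_benign, alpha_benign_strict, power_pathogenic,
            alpha_pathogenic)
  if (any(vals <= 0 | vals >= 1)) {
    abort("all thresholds must lie strictly in (0, 1)")
  }
  structure(list(alpha_benign = alpha_benign,
                 alpha_benign_strict = alpha_benign_strict,
                 power_pathogenic = power_pathogenic,
                 alpha_pathogenic = alpha_pathogenic),
            class = "decision_thresholds")
}

#' Minimum-sample decision table
#'
#' For each cohort size `n` up to `n_max`: the smallest loss-of-WT count
#' `k_min` whose upper tail under the benign rate falls below
#' `alpha_benign` (the risk of reaching it by chance for a neutral
#' variant), with the power of that count under the pathogenic rate; and
#' the largest count `k_max` whose lower tail under the pathogenic rate
#' falls below `alpha_pathogenic` (excluding pathogenicity), with that
#' tail as the miss rate for a truly pathogenic variant. `k_min`/`k_max`
#' are `NA` when no count within `0..n` qualifies.
#'
#' @param p_benign,p_pathogenic Class-conditional loss-of-WT rates.
#' @param n_max Largest cohort size tabulated.
#' @param thresholds A [decision_thresholds()]; set
#'   `alpha_benign = 0.0005` for the strict (class-2 grade) table.
#' @return Tibble with columns `n`, `k_min_exclude_neutrality`,
#'   `risk_at_k_min`, `power_at_k_min`, `k_max_exclude_pathogenicity`,
#'   `miss_rate`.
#' @export
decision_table <- function(p_benign = 6 / 27, p_pathogenic = 36 / 55,
                           n_max = 10, thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  if (n_max < 1) abort("n_max must be >= 1")
  purrr::map_dfr(seq_len(n_max), function(n) {
    risks <- vapply(0:n, tail_ge, numeric(1), n = n, p = p_benign)
    ok <- which(risks < thresholds$alpha_benign)
    k_min <- if (length(ok)) ok[1] - 1L else NA_integer_
    misses <- vapply(0:n, tail_le, numeric(1), n = n, p = p_pathogenic)
    ok2 <- which(misses < thresholds$alpha_pathogenic)
    k_max <- if (length(ok2)) max(ok2) - 1L else NA_integer_
    tibble(
      n = n,
      k_min_exclude_neutrality = k_min,
      risk_at_k_min = if (is.na(k_min)) NA_real_ else risks[k_min + 1],
      power_at_k_min = if (is.na(k_min)) NA_real_ else
        tail_ge(k_min, n, p_pathogenic),
      k_max_exclude_pathogenicity = k_max,
      miss_rate = if (is.na(k_max)) NA_real_ else misses[k_max + 1]
    )
  })
}

#' Evidence-grade suggestion from an observed LOH pattern
#'
#' Grades the observed loss-of-WT pattern: `EXCLUDE_NEUTRALITY_STRONG`
#' when the benign-rate tail is below `alpha_benign_strict`,
#' `EXCLUDE_NEUTRALITY_MODERATE` below `alpha_moderate` (the ~1 percent zone),
#' `EXCLUDE_PATHOGENICITY` when the pathogenic-rate tail is below
#' `alpha_pathogenic`, else `INCONCLUSIVE`. This is prioritization
#' evidence for further workup, not a statistical test, and never returns
#' a definitive class on its own.
#'
#' @inheritParams loh_evidence
#' @param thresholds A [decision_thresholds()].
#' @param alpha_moderate Boundary of the moderate-evidence zone (default
#'   0.01).
#' @return Character scalar suggestion.
#' @examples
#' classify_by_loh(5, 5, p_benign = 5 / 26)  # strong exclusion of neutrality
#' classify_by_loh(1, 1)                     # a single tumor is inconclusive
#' @export
classify_by_loh <- function(k, n, p_benign = 6 / 27, p_pathogenic = 36 / 55,
                            thresholds = decision_thresholds(),
                            alpha_moderate = 0.01) {
  if (n == 0) return("INCONCLUSIVE")
  ev <- loh_evidence(k, n, p_benign, p_pathogenic)
  if (ev$prob_ge_k_given_benign < thresholds$alpha_benign_strict) {
    return("EXCLUDE_NEUTRALITY_STRONG")
  }
  if (ev$prob_ge_k_given_benign < alpha_moderate) {
    return("EXCLUDE_NEUTRALITY_MODERATE")
  }
  if (ev$prob_le_k_given_pathogenic < thresholds$alpha_pathogenic) {
    return("EXCLUDE_PATHOGENICITY")
  }
  "INCONCLUSIVE"
}
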