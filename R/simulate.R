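# Synthetic carrier-cohort simulator: germline heterozygous carriers whose
# tumors undergo a latent second-hit event (loss of the wild-type allele,
# loss of the variant allele, or allelic balance), observed through
# purity-diluted allele fractions with measurement noise.

#' Expected tumor variant-allele fraction under a second-hit event
#'
#' Maps a latent allelic event, tumor purity and the copy-number model of
#' the loss to the expected variant-allele fraction by counting allele
#' copies in the tumor/normal cell mixture. With effective purity
#' \eqn{\rho = purity \times subclonal\_fraction}:
#' \itemize{
#'   \item `BALANCE`: 0.5 regardless of purity;
#'   \item `LOSS_WT`, `DELETION`: \eqn{1/(2-\rho)} (one variant copy per
#'     tumor cell, the wild-type copy physically absent);
#'   \item `LOSS_WT`, `CN_LOH`: \eqn{(1+\rho)/2} (the variant allele
#'     duplicated, total copy number 2);
#'   \item `LOSS_VARIANT`, `DELETION`: \eqn{(1-\rho)/(2-\rho)};
#'   \item `LOSS_VARIANT`, `CN_LOH`: \eqn{(1-\rho)/2}.
#' }
#'
#' @param event One of `"BALANCE"`, `"LOSS_WT"`, `"LOSS_VARIANT"`.
#' @param purity Tumor-cell fraction of the specimen, in \[0, 1\].
#' @param copy_model `"DELETION"` (default) or `"CN_LOH"`.
#' @param subclonal_fraction Fraction of tumor cells carrying the event,
#'   in \[0, 1\]; multiplies purity.
#' @return Expected VAF, a fraction in \[0, 1\]. Vectorized over `event`
#'   and `purity`.
#' @examples
#' expected_vaf("LOSS_WT", purity = 0.5)            # 1/1.5
#' expected_vaf("LOSS_WT", purity = 0.5, copy_model = "CN_LOH")
#' @export
expected_vaf <- function(event, purity, copy_model = "DELETION",
                         subclonal_fraction = 1) {
  event <- match_enum(event, EVENTS, "event")
  copy_model <- match.arg(copy_model, COPY_MODELS)
  check_fraction(purity, "purity")
  check_fraction(subclonal_fraction, "subclonal_fraction")
  rho <- purity * subclonal_fraction
  out <- rep(0.5, length(rho))
  if (copy_model == "DELETION") {
    out[event == "LOSS_WT"] <- (1 / (2 - rho))[event == "LOSS_WT"]
    out[event == "LOSS_VARIANT"] <- ((1 - rho) / (2 - rho))[event == "LOSS_VARIANT"]
  } else {
    out[event == "LOSS_WT"] <- ((1 + rho) / 2)[event == "LOSS_WT"]
    out[event == "LOSS_VARIANT"] <- ((1 - rho) / 2)[event == "LOSS_VARIANT"]
  }
  out
}

match_enum <- function(x, levels, name) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    abort(sprintf("`%s` must be one of %s", name,
                  paste(levels, collapse = ", ")))
  }
  x
}

#' Simulation configuration
#'
#' Bundles and validates the generative conditions for a synthetic cohort.
#' Defaults reproduce the reference-cohort conditions: class-conditional
#' loss-of-WT rates of 0.654 (pathogenic) and 0.222 (benign) with
#' loss-of-variant rates 0.055 and 0.148, tumor purity uniform on
#' 0.30--0.90, pyrosequencing triplicates with replicate sd 0.02, and a
#' deletion copy model.
#'
#' @param n_variants_per_class Variants simulated per classification class.
#' @param samples_per_variant Tumors per variant.
#' @param p_loss_wt_by_class Named vector/list: per-class probability that a
#'   tumor loses the wild-type allele.
#' @param p_loss_variant_by_class Named vector/list: per-class probability
#'   of losing the variant allele. Per class,
#'   `p_loss_wt + p_loss_variant <= 1`; the remainder is allelic balance.
#' @param purity_range Length-2 interval in \[0, 1\] for uniform purity.
#' @param read_depth Total read depth for NGS samples (>= 1).
#' @param pyro_sd Standard deviation of pyrosequencing replicate noise, in
#'   VAF fraction units.
#' @param replicates Pyrosequencing replicates per sample (>= 1).
#' @param copy_model `"DELETION"` or `"CN_LOH"`.
#' @param subclonal_fraction_range Length-2 interval in \[0, 1\].
#' @param method Measurement path, `"PYRO"` or `"NGS"`.
#' @param seed Integer seed; all draws for a cohort flow from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_variants_per_class = 4,
                              samples_per_variant = 5,
                              p_loss_wt_by_class = c(PATHOGENIC = 0.654,
                                                     BENIGN = 0.222),
                              p_loss_variant_by_class = c(PATHOGENIC = 0.055,
                                                          BENIGN = 0.148),
                              purity_range = c(0.3, 0.9),
                              read_depth = 1000,
                              pyro_sd = 0.02,
                              replicates = 3,
                              copy_model = "DELETION",
                              subclonal_fraction_range = c(1, 1),
                              method = "PYRO",
                              seed = 20220117) {
  p_wt <- unlist(p_loss_wt_by_class)
  p_var <- unlist(p_loss_variant_by_class)
  if (is.null(names(p_wt)) || any(names(p_wt) == "")) {
    abort("p_loss_wt_by_class must be named by variant class")
  }
  missing_classes <- setdiff(names(p_wt), names(p_var))
  p_var[missing_classes] <- 0
  p_var <- p_var[names(p_wt)]
  check_fraction(p_wt, "p_loss_wt_by_class")
  check_fraction(p_var, "p_loss_variant_by_class")
  if (any(p_wt + p_var > 1 + 1e-12)) {
    abort("per class, p_loss_wt + p_loss_variant must be <= 1")
  }
  check_fraction(purity_range, "purity_range")
  check_fraction(subclonal_fraction_range, "subclonal_fraction_range")
  if (length(purity_range) != 2 || diff(purity_range) < 0) {
    abort("purity_range must be an ordered length-2 interval")
  }
  if (length(subclonal_fraction_range) != 2 ||
      diff(subclonal_fraction_range) < 0) {
    abort("subclonal_fraction_range must be an ordered length-2 interval")
  }
  if (read_depth < 1) abort("read_depth must be >= 1")
  if (replicates < 1) abort("replicates must be >= 1")
  if (pyro_sd < 0) abort("pyro_sd must be non-negative")
  copy_model <- match.arg(copy_model, COPY_MODELS)
  method <- match.arg(method, METHODS)
  structure(list(
    n_variants_per_class = as.integer(n_variants_per_class),
    samples_per_variant = as.integer(samples_per_variant),
    p_loss_wt_by_class = p_wt,
    p_loss_variant_by_class = p_var,
    purity_range = purity_range,
    read_depth = as.integer(read_depth),
    pyro_sd = pyro_sd,
    replicates = as.integer(replicates),
    copy_model = copy_model,
    subclonal_fraction_range = subclonal_fraction_range,
    method = method,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys match the arguments of [simulation_config()] exactly; absent keys
#' fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(simulation_config, raw)
}

#' Simulate pyrosequencing replicate measurements
#'
#' Gaussian replicate noise around the true allele fraction, clipped to
#' \[0, 1\] (clipping bias is negligible for sd <= 0.05 away from the
#' boundaries).
#'
#' @param true_vaf True allele fraction in \[0, 1\].
#' @param sd Replicate standard deviation (>= 0), fraction units.
#' @param replicates Number of replicates (>= 1).
#' @return Numeric vector of length `replicates`.
#' @export
simulate_pyrosequencing <- function(true_vaf, sd = 0.02, replicates = 3) {
  check_fraction(true_vaf, "true_vaf")
  if (sd < 0) abort("sd must be non-negative")
  if (replicates < 1) abort("replicates must be >= 1")
  pmin(pmax(stats::rnorm(replicates, mean = true_vaf, sd = sd), 0), 1)
}

draw_second_hit <- function(classification, config) {
  p_wt <- config$p_loss_wt_by_class[[classification]]
  p_var <- config$p_loss_variant_by_class[[classification]]
  if (is.null(p_wt)) {
    abort(sprintf("no second-hit rates configured for class %s", classification))
  }
  sample(EVENTS, 1, prob = c(1 - p_wt - p_var, p_wt, p_var))
}

#' Simulate one tumor sample for a carrier of a germline variant
#'
#' Draws the latent second-hit event from the class-conditional rates,
#' purity and subclonal fraction uniformly from their configured ranges,
#' computes the expected VAF under the copy model, and observes it through
#' the configured measurement path: binomial read counts at `read_depth`
#' (NGS) or Gaussian replicates (PYRO). Uses R's global RNG stream; seed
#' via `set.seed()` (or use [simulate_cohort()], which seeds from the
#' config).
#'
#' @param variant One-row tibble (or list) with `variant_id` and
#'   `classification`.
#' @param config A [simulation_config()].
#' @param sample_id Identifier for the new sample.
#' @param tissue Tissue label recorded on the sample.
#' @return One-row samples tibble; `truth_event` records the latent event.
#' @export
simulate_sample <- function(variant, config, sample_id = "S1",
                            tissue = "BREAST") {
  stopifnot(inherits(config, "simulation_config"))
  event <- draw_second_hit(variant$classification, config)
  purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
  subcl <- stats::runif(1, config$subclonal_fraction_range[1],
                        config$subclonal_fraction_range[2])
  ev <- expected_vaf(event, purity, config$copy_model, subcl)
  row <- tibble(
    sample_id = sample_id,
    variant_id = variant$variant_id,
    tissue = tissue,
    cellularity = purity,
    method = config$method,
    replicate_vafs = list(NULL),
    alt_depth = NA_integer_,
    total_depth = NA_integer_,
    germline_vaf = 0.5,
    truth_event = event
  )
  if (config$method == "NGS") {
    row$alt_depth <- stats::rbinom(1, config$read_depth, ev)
    row$total_depth <- config$read_depth
  } else {
    row$replicate_vafs <- list(
      simulate_pyrosequencing(ev, config$pyro_sd, config$replicates))
  }
  row
}

#' Simulate a carrier cohort
#'
#' Generates `n_variants_per_class` variants for every class named in
#' `p_loss_wt_by_class`, each with `samples_per_variant` tumors, seeding
#' the global RNG once from `config$seed` so cohorts are reproducible.
#' Draws are consumed variant by variant, sample by sample (event, purity,
#' subclonal fraction, then measurement noise).
#'
#' @param config A [simulation_config()].
#' @return A [variant_cohort()] whose samples carry `truth_event`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  classes <- names(config$p_loss_wt_by_class)
  variants <- tidyr::expand_grid(
    classification = classes,
    idx = seq_len(config$n_variants_per_class)
  )
  variants <- dplyr::mutate(
    variants,
    variant_id = sprintf("sim_%s_%02d", tolower(.data$classification), .data$idx),
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    effect = "MISSENSE"
  )
  variants <- dplyr::select(variants, "variant_id", "hgvs_c", "hgvs_p",
                            "classification", "effect")
  n <- nrow(variants) * config$samples_per_variant
  sample_id <- character(n); variant_id <- character(n)
  cellularity <- numeric(n); truth <- character(n)
  alt <- rep(NA_integer_, n); tot <- rep(NA_integer_, n)
  reps <- vector("list", n)
  idx <- 0L
  # draw order matches simulate_sample(): per sample, event then purity,
  # subclonal fraction, measurement noise
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    for (j in seq_len(config$samples_per_variant)) {
      idx <- idx + 1L
      event <- draw_second_hit(v$classification, config)
      purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
      subcl <- stats::runif(1, config$subclonal_fraction_range[1],
                            config$subclonal_fraction_range[2])
      ev <- expected_vaf(event, purity, config$copy_model, subcl)
      sample_id[idx] <- sprintf("%s_t%03d", v$variant_id, j)
      variant_id[idx] <- v$variant_id
      cellularity[idx] <- purity
      truth[idx] <- event
      if (config$method == "NGS") {
        alt[idx] <- stats::rbinom(1, config$read_depth, ev)
        tot[idx] <- config$read_depth
      } else {
        reps[[idx]] <- simulate_pyrosequencing(ev, config$pyro_sd,
                                               config$replicates)
      }
    }
  }
  samples <- tibble(
    sample_id = sample_id, variant_id = variant_id, tissue = "BREAST",
    cellularity = cellularity, method = config$method,
    replicate_vafs = reps, alt_depth = alt, total_depth = tot,
    germline_vaf = 0.5, truth_event = truth
  )
  variant_cohort(variants, samples)
}
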