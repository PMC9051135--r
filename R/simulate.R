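# Summary statistics are generated directly at the summary level (normal
# sampling theory): per-SNP standard errors scale as 1/sqrt(2 f (1-f) n),
# the working approximation of every estimator downstream. An
# individual-level path exists only for the GRS cohort (simulate_cohort).

NUCLEOTIDES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# non-palindromic ordered allele pairs
.nonpal_pairs <- local({
  p <- expand.grid(ea = NUCLEOTIDES, oa = NUCLEOTIDES,
                   stringsAsFactors = FALSE)
  p[p$ea != p$oa & COMPLEMENT[p$ea] != p$oa, ]
})

.se_summary <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# two-sided normal p, floored so strong instruments never underflow to an
# (invalid) exact zero
.pval_floor <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Generates one summary table per exposure, one outcome summary table, and a
#' truth record, with the statistical structure assumed by two-sample MR:
#' per-SNP true exposure effects `gamma_jk` drawn from a zero-mean normal with
#' the configured correlation between the first two exposures; outcome
#' effects `beta_Yj = sum_k theta_k gamma_jk + alpha_j + e_j` where `alpha_j`
#' is the configured pleiotropy term; sampling noise and standard errors
#' scaled by the respective study's sample size; allele codings corrupted in
#' the configured fractions (effect/other swap with sign flip and reflected
#' frequency; palindromic A/T and C/G pairs).
#'
#' Each variant is assigned to one exposure's instrument block (block sizes
#' from `n_instruments`); every exposure table nevertheless reports all
#' variants, as a genome-wide summary file would.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `mr_simulation`: a list with
#'   \describe{
#'     \item{exposures}{named list of summary data frames (one per exposure)
#'       with columns `variant_id, effect_allele, other_allele, eaf, beta,
#'       se, pval, n`.}
#'     \item{outcome}{outcome summary data frame, same columns, allele coding
#'       corrupted per config.}
#'     \item{ld}{three-column pairwise r-squared table (`variant_a,
#'       variant_b, r2`), or an empty table when variants are independent.}
#'     \item{truth}{per-variant truth record: block assignment, true
#'       `gamma_jk`, pleiotropy `alpha_j`, noiseless `beta_y_true`,
#'       corruption flags; true `theta` stored in `attr(truth, "theta")`.}
#'   }
#' @examples
#' sim <- simulate_summary_pair(sim_config(
#'   n_instruments = c(childhood = 20, adult = 20), seed = 1))
#' head(sim$outcome)
#' @export
simulate_summary_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  K <- length(config$n_instruments)
  J <- sum(config$n_instruments)
  labels <- names(config$n_instruments)
  theta <- config$true_effects

  variant_id <- sprintf("rs%06d", seq_len(J))
  block <- rep(labels, times = config$n_instruments)

  # allele assignment: palindromic fraction gets A/T or C/G
  n_pal <- round(config$frac_palindromic * J)
  is_pal <- seq_len(J) %in% sample.int(J, n_pal)
  ea <- oa <- character(J)
  if (any(!is_pal)) {
    idx <- sample.int(nrow(.nonpal_pairs), sum(!is_pal), replace = TRUE)
    ea[!is_pal] <- .nonpal_pairs$ea[idx]
    oa[!is_pal] <- .nonpal_pairs$oa[idx]
  }
  if (any(is_pal)) {
    ea[is_pal] <- sample(c("A", "C"), sum(is_pal), replace = TRUE)
    oa[is_pal] <- COMPLEMENT[ea[is_pal]]
  }

  # frequencies: palindromic variants stay away from 0.5 unless the
  # ambiguity stress-test flag is set
  eaf <- stats::runif(J, config$eaf_range[1], config$eaf_range[2])
  if (any(is_pal)) {
    np <- sum(is_pal)
    if (config$ambiguous_palindromes) {
      eaf[is_pal] <- stats::runif(np, 0.42, 0.58)
    } else {
      lo <- max(config$eaf_range[1], 0.10)
      side <- sample(c(-1, 1), np, replace = TRUE)
      f <- stats::runif(np, lo, 0.40)
      eaf[is_pal] <- ifelse(side < 0, f, 1 - f)
    }
  }

  # true per-SNP exposure effects, correlated across the first two exposures
  gamma <- matrix(stats::rnorm(J * K, 0, config$gamma_sd), J, K)
  if (K >= 2 && config$exposure_correlation != 0) {
    rho <- config$exposure_correlation
    gamma[, 2] <- rho * gamma[, 1] + sqrt(1 - rho^2) * gamma[, 2]
  }
  colnames(gamma) <- labels

  # directional pleiotropy acts relative to the exposure-raising allele of
  # the first exposure (as in oriented instrument tables); its magnitude is
  # independent of instrument strength, so the InSIDE assumption holds
  alpha <- switch(config$pleiotropy,
    none        = rep(0, J),
    balanced    = stats::rnorm(J, 0, config$pleiotropy_sd),
    directional = sign(gamma[, 1]) *
      stats::rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd))

  se_x <- .se_summary(eaf, config$n_exposure_sample)
  se_y <- .se_summary(eaf, config$n_outcome_sample)
  beta_y_true <- drop(gamma %*% theta) + alpha

  exposures <- lapply(seq_len(K), function(k) {
    beta <- gamma[, k] + config$noise_scale * stats::rnorm(J, 0, se_x)
    data.frame(variant_id = variant_id, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta, se = se_x,
               pval = .pval_floor(beta / se_x),
               n = config$n_exposure_sample, stringsAsFactors = FALSE)
  })
  names(exposures) <- labels

  beta_y <- beta_y_true + config$noise_scale * stats::rnorm(J, 0, se_y)
  outcome <- data.frame(variant_id = variant_id, effect_allele = ea,
                        other_allele = oa, eaf = eaf, beta = beta_y,
                        se = se_y, pval = .pval_floor(beta_y / se_y),
                        n = config$n_outcome_sample, stringsAsFactors = FALSE)

  # corrupt the outcome table's allele coding: swap alleles, negate beta,
  # reflect eaf. For palindromic variants this is indistinguishable from an
  # opposite-strand report and must be resolved from frequency downstream.
  n_swap <- round(config$frac_allele_swapped * J)
  swapped <- seq_len(J) %in% sample.int(J, n_swap)
  if (any(swapped)) {
    tmp <- outcome$effect_allele[swapped]
    outcome$effect_allele[swapped] <- outcome$other_allele[swapped]
    outcome$other_allele[swapped] <- tmp
    outcome$beta[swapped] <- -outcome$beta[swapped]
    outcome$eaf[swapped] <- 1 - outcome$eaf[swapped]
  }

  truth <- data.frame(variant_id = variant_id, block = block,
                      stringsAsFactors = FALSE)
  for (k in labels) truth[[paste0("gamma_", k)]] <- gamma[, k]
  truth$alpha <- alpha
  truth$beta_y_true <- beta_y_true
  truth$palindromic <- is_pal
  truth$swapped <- swapped
  attr(truth, "theta") <- theta

  ld <- .ld_table(variant_id, config$ld_blocks)

  structure(list(exposures = exposures, outcome = outcome, ld = ld,
                 truth = truth, config = config),
            class = "mr_simulation")
}

.ld_table <- function(variant_id, ld_blocks) {
  empty <- data.frame(variant_a = character(), variant_b = character(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  if (is.null(ld_blocks)) return(empty)
  J <- length(variant_id)
  blk <- ceiling(seq_len(J) / ld_blocks$size)
  pairs <- do.call(rbind, lapply(split(variant_id, blk), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(variant_a = cmb[1, ], variant_b = cmb[2, ],
               r2 = ld_blocks$r2, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) empty else `rownames<-`(pairs, NULL)
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf("Synthetic two-sample GWAS: %d variants, %d exposure table(s)\n",
              nrow(x$outcome), length(x$exposures)))
  cat("  exposures:", paste(names(x$exposures), collapse = ", "), "\n")
  cat(sprintf("  corrupted: %d swapped, %d palindromic\n",
              sum(x$truth$swapped), sum(x$truth$palindromic)))
  invisible(x)
}

#' Simulate an individual-level cohort for genetic risk score analysis
#'
#' Draws genotype dosages per variant from binomial(2, eaf), forms the true
#' weighted score, and generates a continuous BMI-like phenotype
#' `grs_effect * standardized true score + age and sex effects + noise`.
#' Emulates a childhood cohort with clinic ages around 9.9 years.
#'
#' @param config a [sim_config()] object; `n_cohort`, `grs_effect` and
#'   `cohort_noise_sd` control the cohort.
#' @param instruments data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `weight` — one row per scored variant. A
#'   simulation truth record's variants can be passed through
#'   [sim_instrument_set()].
#' @param age_effect,sex_effect covariate effects on the phenotype.
#' @return Object of class `cohort_data`: list with `genotypes` (n x J
#'   dosage matrix, columns keyed by variant id, counted on the effect
#'   allele), `phenotypes` (data frame `bmi, age, sex`), `variants` (the
#'   instrument table) and `truth` (generating slope per 1 SD of score).
#' @export
simulate_cohort <- function(config, instruments,
                            age_effect = 0.05, sex_effect = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "weight")
  if (!all(need %in% names(instruments)))
    stop("`instruments` must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(instruments$variant_id))
    stop("duplicate variant ids in `instruments`")
  if (any(!is.finite(instruments$weight)))
    stop("instrument weights must be finite")
  if (any(instruments$eaf <= 0 | instruments$eaf >= 1))
    stop("instrument frequencies must lie in (0, 1)")

  set.seed(config$seed + 1L)  # distinct stream from the summary generator
  n <- config$n_cohort
  J <- nrow(instruments)

  geno <- vapply(instruments$eaf,
                 function(f) stats::rbinom(n, 2L, f), numeric(n))
  colnames(geno) <- instruments$variant_id

  score <- drop(geno %*% instruments$weight)
  sd_s <- stats::sd(score)
  z <- if (sd_s > 0) (score - mean(score)) / sd_s else score * 0

  age <- stats::runif(n, 8.9, 11.5)
  sex <- stats::rbinom(n, 1L, 0.5)
  bmi <- config$grs_effect * z + age_effect * (age - mean(age)) +
    sex_effect * sex + stats::rnorm(n, 0, config$cohort_noise_sd)

  structure(list(
    genotypes = geno,
    phenotypes = data.frame(bmi = bmi, age = age, sex = sex),
    variants = instruments,
    truth = list(grs_effect = config$grs_effect)
  ), class = "cohort_data")
}

#' Build an instrument set from a simulation
#'
#' Convenience accessor: takes the variants of one exposure's instrument
#' block (or an explicit id list) from a simulation and returns the
#' `variant_id / effect_allele / other_allele / eaf / weight` table used by
#' [simulate_cohort()] and [grs_regression()], with weights taken from the
#' outcome or exposure effect estimates.
#'
#' @param sim an `mr_simulation` object.
#' @param exposure exposure label whose block to use (default: first).
#' @param weights `"outcome"` (log-odds weights from the outcome table,
#'   the liability-score choice) or `"exposure"`.
#' @export
sim_instrument_set <- function(sim, exposure = NULL,
                               weights = c("outcome", "exposure")) {
  stopifnot(inherits(sim, "mr_simulation"))
  weights <- match.arg(weights)
  if (is.null(exposure)) exposure <- names(sim$exposures)[1]
  ids <- sim$truth$variant_id[sim$truth$block == exposure]
  src <- if (weights == "outcome") sim$outcome else sim$exposures[[exposure]]
  rows <- src[match(ids, src$variant_id), ]
  data.frame(variant_id = rows$variant_id,
             effect_allele = rows$effect_allele,
             other_allele = rows$other_allele,
             eaf = rows$eaf, weight = rows$beta,
             stringsAsFactors = FALSE)
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals, %d variants\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}
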