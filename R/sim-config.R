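#' Simulation configuration for synthetic two-sample GWAS data
#'
#' Collects and validates every parameter of the synthetic summary-statistic
#' generator: instrument counts per exposure, true causal effects on the
#' log-odds scale, the genetic correlation between the first two exposures'
#' per-SNP effects, the pleiotropy regime, sample sizes for the exposure and
#' outcome studies, allele-frequency range, allele-corruption fractions,
#' block-LD structure and the master seed.
#'
#' Defaults emulate the scale of the lifecourse body-size analysis this
#' package targets: 280 childhood and 515 adult body-size instruments, an
#' exposure GWAS of 453,169 individuals and a disease outcome study of
#' 173,981, with true direct effects of log(2) for the childhood exposure and
#' zero for the adult exposure.
#'
#' @param n_instruments named integer vector, instruments per exposure
#'   (names become exposure labels). All entries must be positive.
#' @param true_effects named numeric vector of true direct causal effects,
#'   log-odds per unit of each exposure; names must match `n_instruments`.
#' @param exposure_correlation genetic correlation in \[-1, 1\] between the
#'   per-SNP effect vectors of the first two exposures (others independent).
#' @param pleiotropy one of `"none"`, `"balanced"`, `"directional"`: the
#'   distribution of direct SNP-to-outcome effects alpha_j.
#' @param pleiotropy_mean,pleiotropy_sd mean and sd of alpha_j. A non-zero
#'   mean is only allowed when `pleiotropy = "directional"`.
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes (>= 2) used to
#'   scale per-SNP standard errors as 1/sqrt(2 f (1-f) n).
#' @param eaf_range effect-allele frequency range, strictly inside (0, 1).
#' @param frac_palindromic fraction of variants given A/T or C/G alleles.
#' @param frac_allele_swapped fraction of variants whose outcome-table allele
#'   coding is corrupted (effect/other allele swapped, beta negated,
#'   frequency reflected).
#' @param ambiguous_palindromes if `TRUE`, palindromic variants draw their
#'   frequency inside \[0.42, 0.58\] so that harmonisation must drop them;
#'   by default palindromic frequencies are kept away from 0.5 so frequency
#'   inference can resolve strand.
#' @param ld_blocks `NULL` for fully independent variants, or
#'   `list(size = <block size>, r2 = <within-block r-squared>)`.
#' @param gamma_sd sd of the per-SNP true exposure effects. The default
#'   0.25 gives mean instrument F-statistics near 10^4 at the default
#'   exposure sample size, so that weak-instrument attenuation (of order
#'   1/F) stays below the Monte-Carlo resolution of the 200-replicate
#'   parameter-recovery tests — the calibration the effect-size scale is
#'   defined by (see the methods vignette). It is a strong-instrument
#'   stand-in, not a claim about real per-SNP effect magnitudes.
#' @param noise_scale multiplier on all summary-level sampling noise;
#'   0 gives noiseless summary statistics (useful for exact-recovery tests).
#' @param n_cohort,grs_effect,cohort_noise_sd individual-level cohort
#'   parameters for [simulate_cohort()]: cohort size, phenotype effect per
#'   1 SD of the true genetic score, and residual phenotype sd.
#' @param seed master integer seed; every stochastic draw in the generator
#'   derives from this single stream.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_summary_pair()], [simulate_cohort()]
#' @examples
#' cfg <- sim_config(n_instruments = c(childhood = 30, adult = 40),
#'                   true_effects = c(childhood = log(2), adult = 0),
#'                   seed = 7)
#' @export
sim_config <- function(n_instruments = c(childhood = 280, adult = 515),
                       true_effects = stats::setNames(
                         c(log(2), rep(0, length(n_instruments) - 1L)),
                         names(n_instruments)),
                       exposure_correlation = 0.3,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_exposure_sample = 453169,
                       n_outcome_sample = 173981,
                       eaf_range = c(0.05, 0.95),
                       frac_palindromic = 0.1,
                       frac_allele_swapped = 0.2,
                       ambiguous_palindromes = FALSE,
                       ld_blocks = NULL,
                       gamma_sd = 0.25,
                       noise_scale = 1,
                       n_cohort = 5000,
                       grs_effect = 0,
                       cohort_noise_sd = 1,
                       seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)

  if (is.null(names(n_instruments)) || anyDuplicated(names(n_instruments)))
    stop("`n_instruments` must have unique names (exposure labels)")
  if (any(n_instruments < 1) || any(n_instruments != round(n_instruments)))
    stop("instrument counts must be positive integers")
  if (!identical(sort(names(true_effects)), sort(names(n_instruments))))
    stop("`true_effects` names must match `n_instruments` names")
  true_effects <- true_effects[names(n_instruments)]
  if (abs(exposure_correlation) > 1)
    stop("`exposure_correlation` must lie in [-1, 1]")
  if (pleiotropy != "directional" && pleiotropy_mean != 0)
    stop("a non-zero `pleiotropy_mean` requires pleiotropy = \"directional\"")
  if (pleiotropy == "none" && pleiotropy_sd != 0)
    stop("pleiotropy = \"none\" requires `pleiotropy_sd` = 0")
  if (n_exposure_sample < 2 || n_outcome_sample < 2 || n_cohort < 2)
    stop("all sample sizes must be >= 2")
  if (length(eaf_range) != 2 || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] >= eaf_range[2])
    stop("`eaf_range` must be an increasing interval strictly inside (0, 1)")
  if (frac_palindromic < 0 || frac_palindromic > 1 ||
      frac_allele_swapped < 0 || frac_allele_swapped > 1)
    stop("corruption fractions must lie in [0, 1]")
  if (!is.null(ld_blocks)) {
    if (!is.list(ld_blocks) || is.null(ld_blocks$size) || is.null(ld_blocks$r2))
      stop("`ld_blocks` must be NULL or list(size =, r2 =)")
    if (ld_blocks$size > sum(n_instruments))
      stop("LD block size exceeds the total instrument count")
    if (ld_blocks$r2 < 0 || ld_blocks$r2 > 1)
      stop("within-block r2 must lie in [0, 1]")
  }
  if (gamma_sd <= 0) stop("`gamma_sd` must be positive")
  if (noise_scale < 0) stop("`noise_scale` must be non-negative")

  structure(list(
    n_instruments = n_instruments,
    true_effects = true_effects,
    exposure_correlation = exposure_correlation,
    pleiotropy = pleiotropy,
    pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    n_exposure_sample = n_exposure_sample,
    n_outcome_sample = n_outcome_sample,
    eaf_range = eaf_range,
    frac_palindromic = frac_palindromic,
    frac_allele_swapped = frac_allele_swapped,
    ambiguous_palindromes = ambiguous_palindromes,
    ld_blocks = ld_blocks,
    gamma_sd = gamma_sd,
    noise_scale = noise_scale,
    n_cohort = n_cohort,
    grs_effect = grs_effect,
    cohort_noise_sd = cohort_noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic two-sample GWAS configuration\n")
  cat("  exposures:  ",
      paste(sprintf("%s (J=%d, theta=%.3f)", names(x$n_instruments),
                    x$n_instruments, x$true_effects), collapse = ", "), "\n")
  cat("  pleiotropy: ", x$pleiotropy,
      if (x$pleiotropy != "none")
        sprintf(" (mean %.3g, sd %.3g)", x$pleiotropy_mean, x$pleiotropy_sd),
      "\n", sep = "")
  cat(sprintf("  samples:    exposure n=%d, outcome n=%d\n",
              x$n_exposure_sample, x$n_outcome_sample))
  cat(sprintf("  corruption: %.0f%% palindromic, %.0f%% allele-swapped\n",
              100 * x$frac_palindromic, 100 * x$frac_allele_swapped))
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}
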