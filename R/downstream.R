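#' Genetic risk score regression (reverse-direction analysis)
#'
#' Builds a weighted allele score `GRS_i = sum_j weight_j * dosage_ij`
#' (dosages counted on each instrument's effect allele), standardises it to
#' mean 0 / SD 1, and fits ordinary least squares of the phenotype on the
#' standardised score plus covariates. The slope is reported per 1-SD
#' change in the GRS, so it is invariant to rescaling all weights by a
#' positive constant.
#'
#' @param cohort a `cohort_data` object (see [simulate_cohort()]), or a list
#'   with `genotypes` (n x J dosage matrix, columns named by variant id),
#'   `phenotypes` (data frame containing the phenotype and covariates) and
#'   optionally `variants` (with `effect_allele` per variant for coding
#'   checks).
#' @param instruments data frame with `variant_id` and `weight` (and
#'   optionally `effect_allele`, checked against the cohort's coding:
#'   mismatched codings flip the dosage to 2 - g).
#' @param phenotype name of the phenotype column (default `"bmi"`).
#' @param covariates character vector of covariate column names
#'   (default `c("age", "sex")`; use `character(0)` for none).
#' @return Object of class `grs_fit`: slope per 1 SD of GRS, SE, 95% CI,
#'   p-value, n, and the underlying `lm` fit.
#' @export
grs_regression <- function(cohort, instruments, phenotype = "bmi",
                           covariates = c("age", "sex")) {
  geno <- cohort$genotypes
  phen <- cohort$phenotypes
  if (!all(c(phenotype, covariates) %in% names(phen)))
    stop("phenotype/covariate column(s) missing from cohort phenotypes")
  missing_ids <- setdiff(instruments$variant_id, colnames(geno))
  if (length(missing_ids))
    stop("instrument(s) absent from cohort genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  if (any(!is.finite(instruments$weight)))
    stop("instrument weights must be finite")

  g <- geno[, instruments$variant_id, drop = FALSE]
  if (!is.null(cohort$variants$effect_allele) &&
      !is.null(instruments$effect_allele)) {
    coh_ea <- cohort$variants$effect_allele[
      match(instruments$variant_id, cohort$variants$variant_id)]
    flip <- !is.na(coh_ea) & coh_ea != instruments$effect_allele
    if (any(flip)) g[, flip] <- 2 - g[, flip]
  }

  score <- drop(g %*% instruments$weight)
  s <- stats::sd(score)
  if (!is.finite(s) || s == 0)
    stop("zero-variance GRS: weights or genotypes carry no variation")
  z <- (score - mean(score)) / s

  df <- cbind(data.frame(.y = phen[[phenotype]], .grs = z),
              phen[covariates])
  fml <- stats::reformulate(c(".grs", covariates), response = ".y")
  fit <- stats::lm(fml, data = df)
  co <- summary(fit)$coefficients[".grs", ]
  ci <- co[1] + c(-1, 1) * stats::qt(0.975, fit$df.residual) * co[2]

  structure(list(beta = unname(co[1]), se = unname(co[2]),
                 ci_low = ci[1], ci_high = ci[2], pval = unname(co[4]),
                 n = nrow(df), n_snps = nrow(instruments),
                 phenotype = phenotype, covariates = covariates,
                 fit = fit),
            class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("GRS regression on %s (n = %d, %d variants)\n",
              x$phenotype, x$n, x$n_snps))
  cat(sprintf("  beta %.4f per 1-SD GRS (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment over a family of m p-values: sorted
#' ascending, `adj_i = min over k >= i of (p_k * m / k)`, capped at 1.
#' Tests pass when the adjusted value is at or below `q`.
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @param q FDR threshold (default 0.05, the conventional 5% level).
#' @return data frame `pval, fdr, pass` in the input order.
#' @examples
#' bh_fdr(c(9.64e-6, rep(0.5, 13)))$fdr[1]  # 9.64e-6 * 14
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  fdr <- numeric(m)
  fdr[o] <- adj_sorted
  data.frame(pval = pvals, fdr = fdr, pass = fdr <= q)
}

#' Constant-relative-risk category-shift intervention model
#'
#' Given ordered exposure categories with population proportions `p_i`, a
#' relative risk `RR` per one-category increase, and an overall baseline
#' disease prevalence, the bottom-category absolute risk `r` is solved from
#' `prevalence = r * sum_i p_i * RR^i` (categories indexed 0..C-1 from
#' bottom). A simplified intervention then moves a fraction `shift` of the
#' population down from the top category into the one below, and an equal
#' fraction from the second category into the bottom one; prevalence is
#' recomputed with the shifted proportions under the constant-RR
#' assumption (odds ratios treated as approximate relative risks, valid
#' for rare outcomes).
#'
#' The reported percent reduction is computed both from the rounded
#' prevalences as they would be printed (two decimals, in percent) and at
#' full precision.
#'
#' @param proportions ordered category proportions, bottom (lowest-risk)
#'   category first; must sum to 1 (tolerance 1e-12).
#' @param rr relative risk per one-category increase (> 0).
#' @param baseline_prevalence overall disease prevalence in (0, 1).
#' @param shift fraction of the population moved down one category from
#'   the top, with an equal fraction moved from the second category to the
#'   bottom.
#' @return Object of class `intervention_result`: category risk table
#'   (proportions, per-category risk, affected/unaffected composition),
#'   shifted proportions, post-shift prevalence, and percent reductions
#'   (rounded-scale and full-precision).
#' @examples
#' # three body-size categories, RR 2.64 per category, 0.5% prevalence
#' intervention_model(c(0.33, 0.511, 0.159), rr = 2.64,
#'                    baseline_prevalence = 0.005, shift = 0.10)
#' @export
intervention_model <- function(proportions, rr, baseline_prevalence, shift) {
  C <- length(proportions)
  if (C < 2) stop("need at least two categories")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("category proportions must sum to 1")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (rr <= 0) stop("relative risk must be positive")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("baseline prevalence must lie in (0, 1)")
  if (shift < 0) stop("shift must be non-negative")
  if (shift > proportions[C])
    stop("shift exceeds the top-category proportion")
  if (C > 2 && shift > proportions[2])
    stop("shift exceeds the second-category proportion")

  rr_pow <- rr^(seq_len(C) - 1)
  r0 <- baseline_prevalence / sum(proportions * rr_pow)
  risk <- r0 * rr_pow
  if (any(risk >= 1))
    warning("per-category risk exceeds 1; RR approximation breaks down")

  shifted <- proportions
  shifted[C] <- shifted[C] - shift
  shifted[C - 1] <- shifted[C - 1] + shift
  if (C > 2) {
    shifted[2] <- shifted[2] - shift
    shifted[1] <- shifted[1] + shift
  }

  post <- sum(shifted * risk)
  # reduction as printed: percentages rounded to two decimals first
  base_pct <- round(100 * baseline_prevalence, 2)
  post_pct <- round(100 * post, 2)
  reduction_rounded <- 100 * (base_pct - post_pct) / base_pct
  reduction_exact <- 100 * (1 - post / baseline_prevalence)

  category_table <- data.frame(
    category = seq_len(C) - 1L,
    proportion = proportions,
    shifted_proportion = shifted,
    risk = risk,
    prop_affected = proportions * risk / baseline_prevalence,
    prop_unaffected = proportions * (1 - risk) / (1 - baseline_prevalence))

  structure(list(
    category_table = category_table,
    rr = rr, shift = shift,
    baseline_prevalence = baseline_prevalence,
    post_prevalence = post,
    baseline_prevalence_pct = base_pct,
    post_prevalence_pct = post_pct,
    percent_reduction = reduction_rounded,
    percent_reduction_exact = reduction_exact
  ), class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("Category-shift intervention model (constant RR)\n")
  cat(sprintf("  RR per category: %.3f, shift: %.3f\n", x$rr, x$shift))
  print(x$category_table, digits = 4, row.names = FALSE)
  cat(sprintf("  prevalence: %.2f%% -> %.2f%%\n",
              x$baseline_prevalence_pct, x$post_prevalence_pct))
  cat(sprintf("  reduction: %.0f%% (rounded scale), %.2f%% (full precision)\n",
              x$percent_reduction, x$percent_reduction_exact))
  invisible(x)
}
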