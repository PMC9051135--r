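# Independent oracles and tiny fixture builders used across the suite.
# Oracles deliberately route through lm() / p.adjust() / dense-matrix loops
# rather than the package's normal-equation code paths.

# weighted least squares oracle via lm(); returns coefficients and SEs under
# the same multiplicative overdispersion model (floored at the fixed-effect
# SE) that the estimators define
oracle_wls <- function(X, y, w, df_resid) {
  fit <- stats::lm(y ~ 0 + X, weights = w)
  s <- summary(fit)
  sigma2 <- sum(w * stats::residuals(fit)^2) / df_resid
  se_fixed <- s$coefficients[, "Std. Error"] / sqrt(sigma2)
  list(coef = unname(stats::coef(fit)),
       se = unname(se_fixed * sqrt(max(1, sigma2))),
       Q = sum(w * stats::residuals(fit)^2))
}

# cumulative-weight interpolation oracle for the weighted median
oracle_weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

# O(n^2) brute-force greedy clump over a dense r2 matrix
oracle_clump <- function(ids, pvals, r2mat, threshold) {
  ord <- order(pvals, ids)
  retained <- character(0)
  removed <- rep(FALSE, length(ids))
  names(removed) <- ids
  for (i in ord) {
    id <- ids[i]
    if (removed[id]) next
    retained <- c(retained, id)
    for (j in seq_along(ids))
      if (!removed[ids[j]] && r2mat[id, ids[j]] >= threshold)
        removed[ids[j]] <- TRUE
  }
  retained
}

# random single-exposure dataset for estimator oracle checks
random_uni_dataset <- function(J, seed) {
  set.seed(seed)
  harmonized_data(
    beta_x = stats::runif(J, 0.05, 0.5) * sample(c(-1, 1), J, TRUE),
    se_x = stats::runif(J, 0.01, 0.05),
    beta_y = stats::rnorm(J, 0, 0.2),
    se_y = stats::runif(J, 0.02, 0.1))
}

random_mv_dataset <- function(J, K, seed) {
  set.seed(seed)
  harmonized_data(
    beta_x = matrix(stats::rnorm(J * K, 0, 0.2), J, K),
    se_x = matrix(stats::runif(J * K, 0.01, 0.05), J, K),
    beta_y = stats::rnorm(J, 0, 0.2),
    se_y = stats::runif(J, 0.02, 0.1),
    labels = paste0("x", seq_len(K)))
}

# minimal summary-statistic table builder
sumstats_table <- function(variant_id, ea, oa, beta, se = 0.05,
                           eaf = 0.3, n = 10000) {
  J <- length(variant_id)
  data.frame(variant_id = variant_id, effect_allele = ea, other_allele = oa,
             eaf = rep_len(eaf, J), beta = beta, se = rep_len(se, J),
             pval = pmax(2 * stats::pnorm(-abs(beta / rep_len(se, J))),
                         1e-300),
             n = rep_len(n, J), stringsAsFactors = FALSE)
}
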