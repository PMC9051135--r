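# Univariable two-sample MR estimators. All work on the summary level:
# outcome effects regressed on exposure effects with inverse-variance
# weights w_j = 1/se_Yj^2 (first-order weights; no measurement-error
# correction in the exposure effects).

new_mr_estimate <- function(method, theta, se, pval,
                            n_snps, df = NA_real_,
                            Q = NA_real_, Q_df = NA_real_,
                            intercept = NA_real_, se_intercept = NA_real_,
                            pval_intercept = NA_real_,
                            exposure = NA_character_,
                            outcome = NA_character_,
                            ci_quantile = stats::qnorm(0.975)) {
  ci_low <- theta - ci_quantile * se
  ci_high <- theta + ci_quantile * se
  # strong effects can underflow to an exact zero, which downstream
  # consumers (BH adjustment, validation) treat as invalid
  pval <- max(pval, 1e-300)
  if (is.finite(pval_intercept)) pval_intercept <- max(pval_intercept, 1e-300)
  I2 <- if (is.finite(Q) && Q > 0) max(0, (Q - Q_df) / Q) else
    if (is.finite(Q)) 0 else NA_real_
  structure(list(
    method = method, exposure = exposure, outcome = outcome,
    theta = theta, se = se, ci_low = ci_low, ci_high = ci_high,
    pval = pval, or = exp(theta), or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high), n_snps = n_snps, df = df,
    Q = Q, Q_df = Q_df,
    pval_Q = if (is.finite(Q) && is.finite(Q_df) && Q_df > 0)
      stats::pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_,
    I2 = I2,
    intercept = intercept, se_intercept = se_intercept,
    pval_intercept = pval_intercept
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  lab <- c(if (!is.na(x$exposure)) x$exposure,
           if (!is.na(x$outcome)) x$outcome)
  cat(sprintf("MR estimate [%s]%s\n", x$method,
              if (length(lab)) paste0(" ", paste(lab, collapse = " -> "))
              else ""))
  cat(sprintf("  beta %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$theta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR %.3f [%.3f, %.3f], %d SNP(s)\n",
              x$or, x$or_ci_low, x$or_ci_high, x$n_snps))
  if (is.finite(x$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$se_intercept, x$pval_intercept))
  if (is.finite(x$Q))
    cat(sprintf("  Q = %.2f on %g df (p = %.3g), I2 = %.1f%%\n",
                x$Q, x$Q_df, x$pval_Q, 100 * x$I2))
  invisible(x)
}

.single_exposure <- function(dat) {
  m <- .hd_matrices(dat)
  if (ncol(m$beta_x) != 1L)
    stop("this estimator requires a single-exposure dataset")
  list(bx = m$beta_x[, 1], sx = m$se_x[, 1], by = m$beta_y, sy = m$se_y,
       label = m$labels[1])
}

#' Wald ratio causal estimate from a single variant
#'
#' `theta = beta_y / beta_x` with the first-order standard error
#' `se_y / |beta_x|` (no measurement error in the exposure effect).
#'
#' @param beta_x,se_x variant-exposure effect and its standard error.
#' @param beta_y,se_y variant-outcome effect and its standard error.
#' @return An `mr_estimate`.
#' @examples
#' wald_ratio(0.5, 0.05, 0.25, 0.10)  # theta 0.5, se 0.2
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("undefined ratio: beta_x = 0")
  if (se_y <= 0) stop("se_y must be positive")
  theta <- beta_y / beta_x
  se <- se_y / abs(beta_x)
  new_mr_estimate("wald", theta, se,
                  pval = 2 * stats::pnorm(-abs(theta / se)),
                  n_snps = 1L)
}

#' Inverse-variance weighted (IVW) MR estimate
#'
#' Origin-constrained weighted regression of outcome effects on exposure
#' effects: `theta = sum(w bx by) / sum(w bx^2)` with `w = 1/se_y^2`.
#' Under the multiplicative random-effects model (the default) the
#' fixed-effect standard error is inflated by `max(1, sqrt(Q/(J-1)))` where
#' `Q` is Cochran's heterogeneity statistic; the inflation never deflates
#' below the fixed-effect SE. P-values are two-sided normal.
#'
#' @param dat a `harmonized_data` object with one exposure.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with `Q` and `I2` attached.
#' @export
mr_ivw <- function(dat, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  d <- .single_exposure(dat)
  J <- length(d$bx)
  if (J < 1 || (effects_model == "multiplicative_random" && J < 2))
    stop("IVW requires >= 2 variants (>= 1 for the fixed-effect model)")
  if (all(d$bx == 0)) stop("all exposure effects are zero")

  w <- 1 / d$sy^2
  theta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fixed <- sqrt(1 / sum(w * d$bx^2))
  Q <- sum(w * (d$by - theta * d$bx)^2)
  se <- if (effects_model == "multiplicative_random" && J > 1)
    se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  new_mr_estimate(paste0("ivw_", if (effects_model == "fixed") "fe" else "re"),
                  theta, se, pval = 2 * stats::pnorm(-abs(theta / se)),
                  n_snps = J, Q = Q, Q_df = J - 1,
                  exposure = d$label)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an unconstrained
#' intercept, after orienting every variant so its exposure effect is
#' non-negative. The intercept estimates the average directional
#' pleiotropic effect; the slope is a pleiotropy-robust causal estimate
#' under the InSIDE assumption. Slope and intercept standard errors are
#' inflated by `max(1, sqrt(Q_egger/(J-2)))`; p-values use the t
#' distribution with J-2 degrees of freedom.
#'
#' @param dat a `harmonized_data` object with one exposure and >= 3 variants.
#' @return An `mr_estimate` with intercept fields populated.
#' @export
mr_egger <- function(dat) {
  d <- .single_exposure(dat)
  J <- length(d$bx)
  if (J < 3) stop("MR-Egger requires at least 3 variants")

  flip <- d$bx < 0
  bx <- ifelse(flip, -d$bx, d$bx)
  by <- ifelse(flip, -d$by, d$by)
  if (stats::var(bx) == 0)
    stop("unidentified slope: no variance in oriented exposure effects")

  fit <- .wls(cbind(1, bx), by, 1 / d$sy^2, df_resid = J - 2)
  tq <- stats::qt(0.975, J - 2)
  est <- new_mr_estimate(
    "egger", theta = fit$coef[2], se = fit$se[2],
    pval = 2 * stats::pt(-abs(fit$coef[2] / fit$se[2]), J - 2),
    n_snps = J, df = J - 2, Q = fit$Q, Q_df = J - 2,
    intercept = fit$coef[1], se_intercept = fit$se[1],
    pval_intercept = 2 * stats::pt(-abs(fit$coef[1] / fit$se[1]), J - 2),
    exposure = d$label, ci_quantile = tq)
  est
}

# weighted least squares via the normal equations; se inflated by
# max(1, sqrt(Q/df_resid)) — the multiplicative overdispersion model
.wls <- function(X, y, w, df_resid) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  coefs <- unname(drop(solve(XtWX, XtW %*% y)))
  resid <- y - drop(X %*% coefs)
  Q <- sum(w * resid^2)
  phi <- if (df_resid > 0) max(1, Q / df_resid) else 1
  covm <- solve(XtWX) * phi
  list(coef = coefs, se = unname(sqrt(diag(covm))), cov = covm, Q = Q)
}

#' Weighted median MR estimate
#'
#' Per-variant Wald ratios `theta_j = beta_y/beta_x` are combined by taking
#' the weighted 50th percentile, with weights `(beta_x/se_y)^2` (the
#' inverse of the first-order ratio variance) normalised to sum to one. The
#' percentile is computed by linear interpolation of the cumulative weight
#' function across the sorted ratios. The estimate is consistent when
#' variants carrying at least half the weight are valid instruments. The
#' standard error comes from a seeded parametric bootstrap: exposure and
#' outcome effects are resampled from normals with their standard errors
#' and the estimate recomputed.
#'
#' @param dat a `harmonized_data` object with one exposure and >= 3 variants.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed integer seed for the bootstrap (recorded in the output).
#' @return An `mr_estimate`; the bootstrap seed is attached as attribute
#'   `boot_seed`.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = 1L) {
  d <- .single_exposure(dat)
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  zero <- d$bx == 0
  if (any(zero)) {
    warning(sum(zero), " variant(s) with zero exposure effect excluded")
    d <- lapply(d, function(v) if (length(v) > 1) v[!zero] else v)
  }
  J <- length(d$bx)
  if (J == 0) stop("no usable variants: all exposure effects are zero")
  if (J < 3) stop("weighted median requires at least 3 usable variants")

  est <- .weighted_median_est(d$by / d$bx, (d$bx / d$sy)^2)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(J, d$bx, d$sx)
    by <- stats::rnorm(J, d$by, d$sy)
    ok <- bx != 0
    .weighted_median_est(by[ok] / bx[ok], (bx[ok] / d$sy[ok])^2)
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  se <- stats::sd(boots)
  out <- new_mr_estimate("weighted_median", est, se,
                         pval = 2 * stats::pnorm(-abs(est / se)),
                         n_snps = J, exposure = d$label)
  attr(out, "boot_seed") <- seed
  attr(out, "n_boot") <- n_boot
  out
}

# weighted 50th percentile by linear interpolation of the cumulative
# weight function (midpoint convention)
.weighted_median_est <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(b[1])
  if (cw[length(cw)] <= 0.5) return(b[length(b)])
  below <- max(which(cw < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Cochran's Q heterogeneity statistic
#'
#' Computes `Q = sum(w (beta_y - intercept - theta beta_x)^2)` with
#' `w = 1/se_y^2` for a given causal slope (and optional intercept), the
#' chi-square p-value on `J - n_params` degrees of freedom, and the derived
#' heterogeneity fraction `I2 = max(0, (Q - df)/Q)`.
#'
#' @param dat a `harmonized_data` object with one exposure.
#' @param theta causal slope at which residual heterogeneity is evaluated.
#' @param intercept optional intercept (MR-Egger residuals); default 0.
#' @param n_params number of fitted parameters consumed (1 for IVW, 2 for
#'   Egger).
#' @return list with `Q`, `df`, `pval_Q`, `I2`.
#' @export
heterogeneity <- function(dat, theta, intercept = 0, n_params = 1) {
  d <- .single_exposure(dat)
  J <- length(d$bx)
  df <- J - n_params
  if (df <= 0) stop("need more variants than fitted parameters")
  w <- 1 / d$sy^2
  Q <- sum(w * (d$by - intercept - theta * d$bx)^2)
  list(Q = Q, df = df,
       pval_Q = stats::pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) else 0)
}
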