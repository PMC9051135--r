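# Multivariable MR: the outcome effects are regressed jointly on K
# exposures' genetic effects, so each slope is the direct effect of that
# exposure conditional on the others. Weights are 1/se_y^2 as in IVW.

.mvmr_matrices <- function(dat) {
  m <- .hd_matrices(dat)
  if (ncol(m$beta_x) < 1) stop("no exposure columns found")
  m
}

.check_rank <- function(X, labels) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("exposure effect matrix is rank deficient; collinear exposure(s): ",
         paste(bad, collapse = ", "))
  }
  d <- svd(scale(X, center = FALSE), nu = 0, nv = 0)$d
  kappa <- d[1] / d[length(d)]
  if (is.finite(kappa) && kappa > 30)
    warning(sprintf(
      "near-collinear exposure effects (condition number %.1f)", kappa))
  kappa
}

#' Multivariable IVW MR
#'
#' Weighted multivariable regression of outcome effects on the K exposures'
#' effects with weights `1/se_y^2` and no intercept. Each coefficient
#' `theta_k` is the direct effect of exposure k conditional on the others.
#' Standard errors come from the weighted normal equations with
#' multiplicative random-effects inflation `max(1, sqrt(Q/(J-K)))`;
#' p-values use the t distribution with J-K degrees of freedom.
#'
#' @param dat a `harmonized_data` object with K exposure columns
#'   (see [harmonize_multi()] or [harmonized_data()]).
#' @return Object of class `mvmr_model`: per-exposure `mr_estimate`s plus
#'   shared `Q`, `I2` and the exposure-matrix condition number.
#' @export
mvmr_ivw <- function(dat) {
  m <- .mvmr_matrices(dat)
  J <- nrow(m$beta_x); K <- ncol(m$beta_x)
  if (J < K + 1) stop("need at least K + 1 variants for K exposures")
  kappa <- .check_rank(m$beta_x, m$labels)

  df <- J - K
  fit <- .wls(m$beta_x, m$beta_y, 1 / m$se_y^2, df_resid = df)
  tq <- stats::qt(0.975, df)
  estimates <- lapply(seq_len(K), function(k)
    new_mr_estimate("mvmr_ivw", fit$coef[k], fit$se[k],
                    pval = 2 * stats::pt(-abs(fit$coef[k] / fit$se[k]), df),
                    n_snps = J, df = df, Q = fit$Q, Q_df = df,
                    exposure = m$labels[k], ci_quantile = tq))
  names(estimates) <- m$labels
  structure(list(method = "mvmr_ivw", exposures = m$labels,
                 estimates = estimates, n_snps = J, Q = fit$Q, Q_df = df,
                 I2 = if (fit$Q > 0) max(0, (fit$Q - df) / fit$Q) else 0,
                 condition_number = kappa, intercept = NULL),
            class = "mvmr_model")
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] but with an unconstrained intercept after orienting
#' every variant so the focal exposure's effect is non-negative (the whole
#' row — all exposures and the outcome — is negated together, so estimates
#' are invariant to the original orientation). The intercept tests
#' directional pleiotropy with respect to the focal exposure's orientation
#' axis. P-values use the t distribution with J-K-1 degrees of freedom.
#'
#' @inheritParams mvmr_ivw
#' @param focal_exposure label of the exposure defining the orientation
#'   axis (default: the first exposure).
#' @return An `mvmr_model` with intercept fields populated.
#' @export
mvmr_egger <- function(dat, focal_exposure = NULL) {
  m <- .mvmr_matrices(dat)
  J <- nrow(m$beta_x); K <- ncol(m$beta_x)
  if (J < K + 2) stop("need at least K + 2 variants for MVMR-Egger")
  if (is.null(focal_exposure)) focal_exposure <- m$labels[1]
  fk <- match(focal_exposure, m$labels)
  if (is.na(fk)) stop("unknown focal exposure: ", focal_exposure)

  sgn <- ifelse(m$beta_x[, fk] < 0, -1, 1)
  bX <- m$beta_x * sgn
  by <- m$beta_y * sgn
  kappa <- .check_rank(bX, m$labels)
  if (stats::var(bX[, fk]) == 0)
    stop("unidentified slope: no variance in the oriented focal exposure")

  df <- J - K - 1
  fit <- .wls(cbind(`(intercept)` = 1, bX), by, 1 / m$se_y^2, df_resid = df)
  tq <- stats::qt(0.975, df)
  estimates <- lapply(seq_len(K), function(k)
    new_mr_estimate("mvmr_egger", fit$coef[k + 1], fit$se[k + 1],
                    pval = 2 * stats::pt(-abs(fit$coef[k + 1] /
                                                fit$se[k + 1]), df),
                    n_snps = J, df = df, Q = fit$Q, Q_df = df,
                    intercept = fit$coef[1], se_intercept = fit$se[1],
                    pval_intercept =
                      2 * stats::pt(-abs(fit$coef[1] / fit$se[1]), df),
                    exposure = m$labels[k], ci_quantile = tq))
  names(estimates) <- m$labels
  structure(list(method = "mvmr_egger", exposures = m$labels,
                 estimates = estimates, n_snps = J, Q = fit$Q, Q_df = df,
                 I2 = if (fit$Q > 0) max(0, (fit$Q - df) / fit$Q) else 0,
                 condition_number = kappa,
                 intercept = list(estimate = fit$coef[1], se = fit$se[1],
                                  pval = 2 * stats::pt(-abs(fit$coef[1] /
                                                              fit$se[1]), df)),
                 focal_exposure = focal_exposure),
            class = "mvmr_model")
}

#' @export
print.mvmr_model <- function(x, ...) {
  cat(sprintf("Multivariable MR [%s]: %d SNPs, %d exposures\n",
              x$method, x$n_snps, length(x$exposures)))
  for (e in x$exposures) {
    est <- x$estimates[[e]]
    cat(sprintf("  %-12s beta %8.4f (SE %.4f)  OR %.3f [%.3f, %.3f]  p = %.3g\n",
                e, est$theta, est$se, est$or, est$or_ci_low,
                est$or_ci_high, est$pval))
  }
  if (!is.null(x$intercept))
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$intercept$estimate, x$intercept$se, x$intercept$pval))
  cat(sprintf("  Q = %.2f on %g df, I2 = %.1f%%\n", x$Q, x$Q_df, 100 * x$I2))
  invisible(x)
}

#' Decompose a total effect into direct and indirect components
#'
#' Subtracts the multivariable (direct) estimate from the univariable
#' (total) estimate on the log-odds scale: `indirect = total - direct`,
#' with an approximate standard error `sqrt(se_total^2 + se_direct^2)`
#' that assumes independence of the two estimates (flagged as approximate
#' in the output). The qualitative pattern is classified as:
#' \describe{
#'   \item{direct}{the direct-effect CI excludes 0 — the exposure acts on
#'     the outcome conditional on the other exposures.}
#'   \item{mediated}{the total CI excludes 0 but the direct CI includes 0 —
#'     the total effect operates via the other exposure(s).}
#'   \item{none}{the total CI includes 0.}
#' }
#'
#' @param total univariable `mr_estimate` (total effect).
#' @param direct multivariable `mr_estimate` for the same exposure/outcome
#'   (direct effect).
#' @return Object of class `effect_decomposition`.
#' @export
decompose_effects <- function(total, direct) {
  stopifnot(inherits(total, "mr_estimate"), inherits(direct, "mr_estimate"))
  if (!is.na(total$exposure) && !is.na(direct$exposure) &&
      total$exposure != direct$exposure)
    stop("total and direct estimates refer to different exposures (",
         total$exposure, " vs ", direct$exposure, ")")

  indirect <- total$theta - direct$theta
  se_ind <- sqrt(total$se^2 + direct$se^2)  # independence approximation
  excl0 <- function(e) e$ci_low > 0 || e$ci_high < 0
  classification <- if (excl0(direct)) "direct"
    else if (excl0(total)) "mediated" else "none"

  structure(list(
    exposure = total$exposure,
    total = total, direct = direct,
    indirect = indirect, se_indirect = se_ind,
    ci_indirect = indirect + c(-1, 1) * stats::qnorm(0.975) * se_ind,
    se_is_approximate = TRUE,
    classification = classification
  ), class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("Effect decomposition",
      if (!is.na(x$exposure)) paste0("(", x$exposure, ")"), "\n")
  cat(sprintf("  total    %8.4f (SE %.4f)\n", x$total$theta, x$total$se))
  cat(sprintf("  direct   %8.4f (SE %.4f)\n", x$direct$theta, x$direct$se))
  cat(sprintf("  indirect %8.4f (approx SE %.4f)\n", x$indirect,
              x$se_indirect))
  cat("  pattern: ", x$classification, "\n")
  invisible(x)
}
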