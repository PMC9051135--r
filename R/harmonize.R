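.is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns the two tables so exposure and outcome effects refer to the same
#' effect allele, variant by variant:
#' \itemize{
#'   \item identical coding — retained unchanged (`aligned`);
#'   \item swapped alleles — outcome beta negated, frequency reflected
#'     (`flipped`);
#'   \item opposite-strand coding of a non-palindromic variant — resolved by
#'     complementing alleles, then as above;
#'   \item palindromic (A/T, C/G) variants — allele letters cannot resolve
#'     strand, so reported frequencies are compared: both must fall outside
#'     the ambiguity band, and when they sit on opposite sides of 0.5 the
#'     outcome is sign-corrected (`palindromic_resolved`); otherwise the
#'     variant is dropped (`palindromic_ambiguous`, or
#'     `palindromic_missing_eaf`);
#'   \item irreconcilable allele pairs dropped (`allele_mismatch`); variants
#'     absent from either table dropped (`absent_outcome` /
#'     `absent_exposure`).
#' }
#'
#' @param exposure,outcome summary-statistic data frames (see
#'   [read_sumstats()]); validated on entry.
#' @param eaf_ambiguity_band frequency interval around 0.5 within which a
#'   palindromic variant's strand is considered unresolvable. Default
#'   `c(0.42, 0.58)`.
#' @return Object of class `harmonized_data`: a data frame with one row per
#'   retained variant and columns `variant_id`, `beta_x`, `se_x`, `pval_x`,
#'   `beta_y`, `se_y`, `eaf`, `action`. Drop records (variant id + reason)
#'   are in `attr(, "drops")`; exposure labels in `attr(, "exposures")`.
#' @examples
#' sim <- simulate_summary_pair(sim_config(
#'   n_instruments = c(childhood = 25), frac_palindromic = 0.2, seed = 3))
#' h <- harmonize(sim$exposures$childhood, sim$outcome)
#' table(h$action)
#' @export
harmonize <- function(exposure, outcome, eaf_ambiguity_band = c(0.42, 0.58)) {
  exposure <- validate_sumstats(exposure, check_pval = FALSE)
  outcome <- validate_sumstats(outcome, check_pval = FALSE)
  if (length(eaf_ambiguity_band) != 2 ||
      eaf_ambiguity_band[1] > eaf_ambiguity_band[2])
    stop("`eaf_ambiguity_band` must be an interval")

  drops <- list()
  add_drop <- function(ids, reason) {
    if (length(ids))
      drops[[length(drops) + 1L]] <<-
        data.frame(variant_id = ids, reason = reason,
                   stringsAsFactors = FALSE)
  }

  add_drop(setdiff(exposure$variant_id, outcome$variant_id), "absent_outcome")
  add_drop(setdiff(outcome$variant_id, exposure$variant_id), "absent_exposure")
  ids <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(ids) == 0)
    stop("no variants shared between exposure and outcome tables")

  ex <- exposure[match(ids, exposure$variant_id), ]
  ou <- outcome[match(ids, outcome$variant_id), ]

  beta_y <- ou$beta
  eaf_y <- ou$eaf
  action <- character(length(ids))
  keep <- rep(TRUE, length(ids))

  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_along(ids)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]

    if (pal[i]) {
      # palindromic on the exposure side: any matching pair letterings are
      # ambiguous; resolve from frequency alone
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        keep[i] <- FALSE; action[i] <- "allele_mismatch"; next
      }
      f_x <- ex$eaf[i]; f_y <- eaf_y[i]
      if (is.na(f_x) || is.na(f_y)) {
        keep[i] <- FALSE; action[i] <- "palindromic_missing_eaf"; next
      }
      # textual swap first, so both frequencies describe the same letter
      if (ea_y == oa_x) { beta_y[i] <- -beta_y[i]; f_y <- 1 - f_y }
      in_band <- function(f) f >= eaf_ambiguity_band[1] &
        f <= eaf_ambiguity_band[2]
      if (in_band(f_x) || in_band(f_y)) {
        keep[i] <- FALSE; action[i] <- "palindromic_ambiguous"; next
      }
      if ((f_x < 0.5) != (f_y < 0.5)) {
        # frequencies disagree on which allele is minor: opposite strand
        beta_y[i] <- -beta_y[i]; f_y <- 1 - f_y
      }
      eaf_y[i] <- f_y
      action[i] <- "palindromic_resolved"
    } else {
      if (ea_y == ea_x && oa_y == oa_x) {
        action[i] <- "aligned"
      } else if (ea_y == oa_x && oa_y == ea_x) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "flipped"
      } else {
        # try the opposite strand for non-palindromic pairs
        cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
        if (identical(cea, ea_x) && identical(coa, oa_x)) {
          action[i] <- "aligned"
        } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
          beta_y[i] <- -beta_y[i]
          eaf_y[i] <- 1 - eaf_y[i]
          action[i] <- "flipped"
        } else {
          keep[i] <- FALSE; action[i] <- "allele_mismatch"
        }
      }
    }
  }

  add_drop(ids[!keep], action[!keep])
  dat <- data.frame(variant_id = ids,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
                    beta_y = beta_y, se_y = ou$se,
                    eaf = ex$eaf, eaf_outcome = eaf_y,
                    action = action, stringsAsFactors = FALSE)[keep, ]
  rownames(dat) <- NULL
  if (nrow(dat) == 0) stop("no variants retained after harmonisation")

  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(dat, class = c("harmonized_data", "data.frame"),
            drops = drops, exposures = "exposure", n_exposures = 1L)
}

#' Harmonise several exposures and one outcome for multivariable MR
#'
#' Uses the first exposure's allele coding as reference, aligns the outcome
#' and every further exposure to it with the same rules as [harmonize()],
#' and keeps the variants retained in every pairwise alignment. The result
#' carries one `beta_x.<label>` / `se_x.<label>` column pair per exposure.
#'
#' @param exposures named list of summary-statistic data frames.
#' @param outcome outcome summary-statistic data frame.
#' @inheritParams harmonize
#' @return `harmonized_data` object with K exposure columns.
#' @export
harmonize_multi <- function(exposures, outcome,
                            eaf_ambiguity_band = c(0.42, 0.58)) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  if (is.null(names(exposures)) || anyDuplicated(names(exposures)))
    stop("`exposures` must be a uniquely named list")
  labels <- names(exposures)

  ref <- harmonize(exposures[[1]], outcome, eaf_ambiguity_band)
  pieces <- list(ref)
  if (length(exposures) > 1) {
    for (k in 2:length(exposures)) {
      # align exposure k to the reference exposure's coding by treating it
      # as the "outcome" of a pairwise harmonisation
      pieces[[k]] <- harmonize(exposures[[1]], exposures[[k]],
                               eaf_ambiguity_band)
    }
  }
  ids <- Reduce(intersect, lapply(pieces, `[[`, "variant_id"))
  if (length(ids) == 0) stop("no variants shared across all exposures")

  out <- ref[match(ids, ref$variant_id),
             c("variant_id", "effect_allele", "other_allele",
               "beta_y", "se_y", "eaf", "action")]
  for (k in seq_along(labels)) {
    if (k == 1) {
      src <- ref[match(ids, ref$variant_id), ]
      out[[paste0("beta_x.", labels[1])]] <- src$beta_x
      out[[paste0("se_x.", labels[1])]] <- src$se_x
      out[[paste0("pval_x.", labels[1])]] <- src$pval_x
    } else {
      src <- pieces[[k]][match(ids, pieces[[k]]$variant_id), ]
      # exposure k's aligned effect sits in the pairwise "outcome" slot
      out[[paste0("beta_x.", labels[k])]] <- src$beta_y
      out[[paste0("se_x.", labels[k])]] <- src$se_y
      out[[paste0("pval_x.", labels[k])]] <- NA_real_
    }
  }
  rownames(out) <- NULL
  drops <- unique(do.call(rbind, lapply(pieces, attr, "drops")))
  structure(out, class = c("harmonized_data", "data.frame"),
            drops = drops, exposures = labels,
            n_exposures = length(labels))
}

#' Extract the exposure effect matrix of a harmonised dataset
#' @param dat a `harmonized_data` object.
#' @return list with `beta_x` (J x K matrix), `se_x` (J x K matrix),
#'   `beta_y`, `se_y`, `labels`.
#' @keywords internal
.hd_matrices <- function(dat) {
  labels <- attr(dat, "exposures")
  if (is.null(labels)) labels <- "exposure"
  if (attr_or(dat, "n_exposures", 1L) == 1L && "beta_x" %in% names(dat)) {
    bx <- matrix(dat$beta_x, ncol = 1, dimnames = list(NULL, labels))
    sx <- matrix(dat$se_x, ncol = 1, dimnames = list(NULL, labels))
  } else {
    bx <- as.matrix(dat[paste0("beta_x.", labels)])
    sx <- as.matrix(dat[paste0("se_x.", labels)])
    colnames(bx) <- colnames(sx) <- labels
  }
  list(beta_x = bx, se_x = sx, beta_y = dat$beta_y, se_y = dat$se_y,
       labels = labels)
}

attr_or <- function(x, which, default) {
  v <- attr(x, which, exact = TRUE)
  if (is.null(v)) default else v
}

#' Construct a harmonised dataset directly from effect vectors
#'
#' Bypasses allele handling — useful for estimator tests and for users whose
#' data are already aligned. `beta_x`/`se_x` may be vectors (one exposure)
#' or matrices with one column per exposure.
#'
#' @param beta_x,se_x exposure effects and standard errors.
#' @param beta_y,se_y outcome effects and standard errors.
#' @param variant_id optional ids (default `snp1..snpJ`).
#' @param labels exposure labels (default from matrix column names).
#' @export
harmonized_data <- function(beta_x, se_x, beta_y, se_y,
                            variant_id = NULL, labels = NULL) {
  bx <- as.matrix(beta_x); sx <- as.matrix(se_x)
  J <- nrow(bx); K <- ncol(bx)
  stopifnot(nrow(sx) == J, ncol(sx) == K,
            length(beta_y) == J, length(se_y) == J)
  if (any(se_y <= 0) || any(sx <= 0)) stop("standard errors must be positive")
  if (is.null(labels))
    labels <- colnames(bx) %||% paste0("exposure", seq_len(K))
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(J))

  out <- data.frame(variant_id = variant_id, stringsAsFactors = FALSE)
  if (K == 1L) {
    out$beta_x <- bx[, 1]; out$se_x <- sx[, 1]
    out$pval_x <- 2 * stats::pnorm(-abs(bx[, 1] / sx[, 1]))
  } else {
    for (k in seq_len(K)) {
      out[[paste0("beta_x.", labels[k])]] <- bx[, k]
      out[[paste0("se_x.", labels[k])]] <- sx[, k]
    }
  }
  out$beta_y <- beta_y; out$se_y <- se_y
  structure(out, class = c("harmonized_data", "data.frame"),
            drops = data.frame(variant_id = character(),
                               reason = character(),
                               stringsAsFactors = FALSE),
            exposures = labels, n_exposures = K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("Harmonised dataset: %d variants, %d exposure(s) [%s]\n",
              nrow(x), attr_or(x, "n_exposures", 1L),
              paste(attr_or(x, "exposures", "exposure"), collapse = ", ")))
  drops <- attr(x, "drops")
  if (!is.null(drops) && nrow(drops)) {
    tab <- table(drops$reason)
    cat("  dropped:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... and", nrow(x) - 6L, "more variants\n")
  invisible(x)
}
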