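# TSV dialect shared by the whole package:
#   variant_id  effect_allele  other_allele  eaf  beta  se  pval  n
# LD reference: variant_a  variant_b  r2  (missing pairs mean r2 = 0).

SUMSTAT_COLS <- c("variant_id", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

#' Read and validate a GWAS summary-statistic table
#'
#' Reads the tab-separated dialect written by [write_sumstats()] /
#' [simulate_summary_pair()] and applies the record-level checks: unique
#' variant ids, single-nucleotide biallelic alleles (indels and
#' multi-allelic records are rejected with a logged count), positive
#' standard errors, p-values in (0, 1\], frequencies in (0, 1) or missing.
#' A warn-only consistency check compares each reported p-value with the
#' two-sided normal p implied by beta/se.
#'
#' @param path TSV file path.
#' @param check_pval warn when reported and implied p-values disagree
#'   beyond rounding (default TRUE).
#' @return A validated data frame of summary-statistic records; the number
#'   of rejected non-biallelic records is attached as attribute
#'   `n_rejected`.
#' @export
read_sumstats <- function(path, check_pval = TRUE) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  validate_sumstats(x, check_pval = check_pval)
}

#' @rdname read_sumstats
#' @param x a data frame of summary-statistic records.
#' @export
validate_sumstats <- function(x, check_pval = TRUE) {
  miss <- setdiff(SUMSTAT_COLS, names(x))
  if (length(miss))
    stop("summary-statistic table lacks columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$variant_id))
    stop("duplicate variant ids: ",
         paste(unique(x$variant_id[duplicated(x$variant_id)])[1:3],
               collapse = ", "))

  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)

  # estimators assume biallelic SNP coding: drop indels / multi-allelics
  ok <- x$effect_allele %in% NUCLEOTIDES & x$other_allele %in% NUCLEOTIDES &
    x$effect_allele != x$other_allele
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected,
            " non-biallelic-SNP record(s) rejected at read time")
    x <- x[ok, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("no valid summary-statistic records")

  if (any(x$se <= 0)) stop("standard errors must be positive")
  if (any(x$pval <= 0 | x$pval > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  if (any(x$eaf <= 0 | x$eaf >= 1, na.rm = TRUE))
    stop("allele frequencies must lie in (0, 1)")

  if (check_pval) {
    implied <- 2 * stats::pnorm(-abs(x$beta / x$se))
    bad <- is.finite(x$pval) &
      abs(log10(pmax(implied, 1e-300)) - log10(pmax(x$pval, 1e-300))) > 1
    if (any(bad))
      warning(sum(bad), " record(s) have p-values inconsistent with beta/se")
  }
  rownames(x) <- NULL
  attr(x, "n_rejected") <- n_rejected
  x
}

#' Write a summary-statistic or LD table as TSV
#' @param x data frame to write.
#' @param path output file path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise LD reference table
#'
#' Three tab-separated columns `variant_a, variant_b, r2`; pairs absent from
#' the table are treated as r-squared 0 by [clump()]. The table is taken as
#' complete truth — no reference-panel computation is performed.
#' @param path TSV file path.
#' @export
read_ld_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  validate_ld_table(x)
}

#' @rdname read_ld_table
#' @param x data frame with columns `variant_a, variant_b, r2`.
#' @export
validate_ld_table <- function(x) {
  if (!all(c("variant_a", "variant_b", "r2") %in% names(x)))
    stop("LD table must have columns variant_a, variant_b, r2")
  if (nrow(x) && any(x$r2 < 0 | x$r2 > 1))
    stop("r2 values must lie in [0, 1]")
  x
}
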