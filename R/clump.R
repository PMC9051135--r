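#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the remaining candidate with the smallest p-value,
#' retains it, and removes every remaining candidate whose reference
#' r-squared with it is at or above the threshold. Pairs absent from the LD
#' table count as r-squared 0. Ties on p-value break lexicographically on
#' variant id, so the output is deterministic. The retained set is verified
#' post-hoc to contain no pair at or above the threshold.
#'
#' @param candidates data frame with at least `variant_id` and `pval`.
#' @param ld pairwise r-squared table (`variant_a, variant_b, r2`); treated
#'   as complete truth.
#' @param r2_threshold clumping threshold in (0, 1\]; default 0.001, the
#'   conventional strict cutoff for MR instrument selection.
#' @return Character vector of retained variant ids, in retention order.
#' @examples
#' cand <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
#'                    pval = c(1e-10, 1e-8, 1e-9))
#' ld <- data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 0.9)
#' clump(cand, ld)  # rs1 shadows rs2
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.001) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("`r2_threshold` must lie in (0, 1]")
  if (!all(c("variant_id", "pval") %in% names(candidates)))
    stop("`candidates` needs columns variant_id and pval")
  if (anyDuplicated(candidates$variant_id))
    stop("duplicate candidate variant ids")
  if (is.null(ld))
    ld <- data.frame(variant_a = character(), variant_b = character(),
                     r2 = numeric())
  ld <- validate_ld_table(ld)

  ord <- order(candidates$pval, candidates$variant_id)
  queue <- candidates$variant_id[ord]

  # symmetric neighbour lookup restricted to pairs at/above threshold
  hot <- ld[ld$r2 >= r2_threshold, , drop = FALSE]
  nbr <- split(c(hot$variant_b, hot$variant_a),
               c(hot$variant_a, hot$variant_b))

  retained <- character(0)
  alive <- stats::setNames(rep(TRUE, length(queue)), queue)
  for (id in queue) {
    if (!alive[[id]]) next
    retained <- c(retained, id)
    kill <- intersect(nbr[[id]], names(alive))
    if (length(kill)) alive[kill] <- FALSE
    alive[[id]] <- FALSE
  }

  # invariant: retained set is mutually independent at the threshold
  bad <- hot$variant_a %in% retained & hot$variant_b %in% retained
  if (any(bad))
    stop("internal error: clumped output contains a dependent pair")
  retained
}

#' Aggregated clumping across several exposures' candidate sets
#'
#' For multivariable MR the instruments of all exposures must be mutually
#' independent, not just independent within each exposure. The per-exposure
#' candidate sets are therefore pooled — each variant carrying its minimum
#' p-value across the exposures that nominate it — and clumped as one set.
#'
#' @param candidate_sets named list of candidate data frames
#'   (`variant_id`, `pval`).
#' @inheritParams clump
#' @return Character vector of retained variant ids (retention order); the
#'   pooled candidate table is attached as attribute `pooled`.
#' @export
clump_multi <- function(candidate_sets, ld = NULL, r2_threshold = 0.001) {
  stopifnot(is.list(candidate_sets), length(candidate_sets) >= 1)
  pooled <- do.call(rbind, lapply(candidate_sets, function(x)
    x[c("variant_id", "pval")]))
  pooled <- stats::aggregate(pval ~ variant_id, data = pooled, FUN = min)
  retained <- clump(pooled, ld, r2_threshold)
  attr(retained, "pooled") <- pooled
  retained
}

#' Select genome-wide significant instruments
#'
#' Filters a summary table at the instrument p-value threshold (default the
#' conventional genome-wide 5e-8) before clumping.
#' @param sumstats summary-statistic data frame.
#' @param p_threshold instrument selection threshold.
#' @export
select_instruments <- function(sumstats, p_threshold = 5e-8) {
  if (p_threshold <= 0 || p_threshold > 1)
    stop("`p_threshold` must lie in (0, 1]")
  out <- sumstats[sumstats$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
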