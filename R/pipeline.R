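# Configuration-driven orchestration of the full analysis graph:
# instrument selection -> harmonisation -> clumping (single and aggregated)
# -> univariable estimators per exposure x outcome -> multivariable MR ->
# decomposition -> reverse GRS -> BH FDR -> intervention model.
# Config files are JSON; every output table carries the config hash and
# seed so a rerun with the same config is bit-identical.

#' Tidy one or more MR estimates into the package's estimate-table format
#'
#' One row per exposure x outcome x method with the columns needed to
#' regenerate forest plots: `exposure, outcome, method, n_snps, beta, se,
#' or, or_lcl, or_ucl, pval, egger_intercept, egger_intercept_pval, Q, I2`.
#'
#' @param x an `mr_estimate`, `mvmr_model`, or list of either.
#' @param exposure,outcome labels used when the estimate carries none.
#' @return data frame in tidy estimate format.
#' @export
tidy_estimates <- function(x, exposure = NA_character_,
                           outcome = NA_character_) {
  row1 <- function(e, exp_label, out_label) {
    data.frame(
      exposure = if (!is.na(exp_label)) exp_label
        else if (!is.na(e$exposure) && e$exposure != "exposure") e$exposure
        else NA_character_,
      outcome = if (!is.na(out_label)) out_label else e$outcome,
      method = e$method, n_snps = e$n_snps,
      beta = e$theta, se = e$se,
      or = e$or, or_lcl = e$or_ci_low, or_ucl = e$or_ci_high,
      pval = e$pval,
      egger_intercept = e$intercept,
      egger_intercept_pval = e$pval_intercept,
      Q = e$Q, I2 = e$I2, stringsAsFactors = FALSE)
  }
  if (inherits(x, "mr_estimate")) return(row1(x, exposure, outcome))
  if (inherits(x, "mvmr_model"))
    return(do.call(rbind, lapply(x$estimates, row1, exp_label = exposure,
                                 out_label = outcome)))
  if (is.list(x))
    return(do.call(rbind, lapply(x, tidy_estimates, exposure = exposure,
                                 outcome = outcome)))
  stop("cannot tidy object of class ", class(x)[1])
}

#' Build a plot-ready forest table
#'
#' One row per exposure x outcome x method with the odds ratio, its 95% CI
#' and a fill flag that is `TRUE` exactly when the CI strictly excludes the
#' null OR of 1 (a CI touching 1.0 is not filled) — the convention of
#' filling forest-plot points whose intervals do not overlap the null.
#'
#' @param estimates tidy estimate data frame (see [tidy_estimates()]).
#' @return The table with columns `or, or_lcl, or_ucl, fill` (plus the
#'   identifying columns present in the input).
#' @export
make_forest_table <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0)
    stop("empty estimate table")
  need <- c("or", "or_lcl", "or_ucl")
  if (!all(need %in% names(estimates)))
    stop("estimate table lacks OR columns")
  estimates$fill <- estimates$or_lcl > 1 | estimates$or_ucl < 1
  estimates
}

# FNV-1a 32-bit hash over the serialized config; avoids an extra dependency
# and is stable within one R version (the only reproducibility contract
# the pipeline makes).
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in
    # double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read / write an individual-level cohort as TSV
#'
#' One row per individual: phenotype and covariate columns first
#' (`bmi, age, sex`), then one dosage column per variant keyed by
#' variant id.
#' @param cohort a `cohort_data` object.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- cbind(cohort$phenotypes, as.data.frame(cohort$genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @param pheno_cols names of the phenotype/covariate columns.
#' @export
read_cohort_tsv <- function(path, pheno_cols = c("bmi", "age", "sex")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  geno_cols <- setdiff(names(df), pheno_cols)
  structure(list(genotypes = as.matrix(df[geno_cols]),
                 phenotypes = df[intersect(pheno_cols, names(df))],
                 variants = NULL, truth = NULL),
            class = "cohort_data")
}

pipeline_defaults <- function() {
  list(
    instrument_p = 5e-8,
    clump_r2 = 0.001,
    eaf_ambiguity_band = c(0.42, 0.58),
    fdr_q = 0.05,
    effects_model = "multiplicative_random",
    n_boot = 1000,
    analyses = list(univariable = TRUE, multivariable = TRUE,
                    reverse = FALSE, intervention = FALSE),
    seed = 1L
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(config_error("config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- pipeline_defaults()
  for (nm in names(def))
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
  for (nm in names(def$analyses))
    if (is.null(config$analyses[[nm]]))
      config$analyses[[nm]] <- def$analyses[[nm]]
  config
}

config_error <- function(...) {
  structure(class = c("lmr_config_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1)))
}

#' Run the full lifecourse MR pipeline
#'
#' Executes, according to the config's analysis flags: instrument selection
#' at the configured p-value threshold, harmonisation of each exposure with
#' each outcome, LD clumping (per-exposure for univariable analyses and
#' aggregated across exposures for multivariable MR), the three univariable
#' estimators, multivariable IVW and Egger with effect decomposition for
#' the focal exposure, reverse-direction GRS regression, BH-FDR over all
#' multivariable slope p-values, and the intervention prevalence model.
#' Result tables are written as TSV to the run directory; each carries the
#' config hash and seed, so a rerun with an identical config is
#' bit-identical.
#'
#' The config is a JSON file or list with blocks: either `simulate`
#' (arguments to [sim_config()]) or `exposures` / `outcomes`
#' (label -> file path maps) plus optional `ld`; thresholds
#' (`instrument_p`, `clump_r2`, `eaf_ambiguity_band`, `fdr_q`); estimator
#' settings (`effects_model`, `n_boot`, `seed`); `analyses` flags
#' (`univariable`, `multivariable`, `reverse`, `intervention`);
#' an `intervention` scenario block (`proportions`, `rr`,
#' `baseline_prevalence`, `shift`); and a `reverse` block
#' (`cohort` TSV path, `instruments` TSV path) — when the config simulates
#' its data the reverse GRS cohort is simulated too.
#'
#' @param config list or JSON file path.
#' @param out_dir run directory for result tables (created if needed);
#'   overrides `config$out_dir`.
#' @return (invisibly) a list of the result tables, with the run directory
#'   as attribute `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("lmr_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  seed <- as.integer(cfg$seed)

  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stamp <- function(df) {
    df$config_hash <- hash
    df$seed <- seed
    df
  }
  emit <- function(df, name) {
    utils::write.table(stamp(df), file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  results <- list()

  ## ---- inputs ----------------------------------------------------------
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$n_instruments <- unlist(sim_args$n_instruments)
    sim_args$true_effects <- unlist(sim_args$true_effects)
    if (!is.null(sim_args$ld_blocks))
      sim_args$ld_blocks <- as.list(sim_args$ld_blocks)
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    sim <- simulate_summary_pair(sim)
    exposures <- sim$exposures
    outcomes <- list(outcome = sim$outcome)
    ld <- sim$ld
    say("stage simulate: %d variants, %d exposures",
        nrow(sim$outcome), length(exposures))
  } else {
    if (is.null(cfg$exposures) || is.null(cfg$outcomes))
      stop(config_error("config must provide `simulate` or both ",
                        "`exposures` and `outcomes`"))
    exposures <- lapply(cfg$exposures, read_sumstats)
    outcomes <- lapply(cfg$outcomes, read_sumstats)
    if (anyDuplicated(c(names(exposures), names(outcomes))))
      stop(config_error("exposure/outcome labels must be unique"))
    ld <- if (!is.null(cfg$ld)) read_ld_table(cfg$ld) else NULL
  }

  ## ---- instrument selection and clumping -------------------------------
  candidates <- lapply(exposures, select_instruments, cfg$instrument_p)
  for (lab in names(candidates))
    say("stage instruments[%s]: %d candidates at p < %g",
        lab, nrow(candidates[[lab]]), cfg$instrument_p)
  kept <- lapply(candidates, function(x) clump(x, ld, cfg$clump_r2))
  kept_multi <- clump_multi(candidates, ld, cfg$clump_r2)
  for (lab in names(kept))
    say("stage clump[%s]: %d retained", lab, length(kept[[lab]]))
  say("stage clump[aggregated]: %d retained", length(kept_multi))

  band <- unlist(cfg$eaf_ambiguity_band)
  uni_rows <- list()
  drop_rows <- list()

  for (out_lab in names(outcomes)) {
    outc <- outcomes[[out_lab]]

    if (isTRUE(cfg$analyses$univariable)) {
      for (exp_lab in names(exposures)) {
        cand <- candidates[[exp_lab]]
        cand <- cand[cand$variant_id %in% kept[[exp_lab]], ]
        h <- harmonize(cand, outc, band)
        drops <- attr(h, "drops")
        if (nrow(drops)) {
          drops$exposure <- exp_lab; drops$outcome <- out_lab
          drop_rows[[length(drop_rows) + 1L]] <- drops
        }
        say("stage harmonize[%s~%s]: %d retained, %d dropped",
            exp_lab, out_lab, nrow(h), nrow(drops))
        ests <- list(
          mr_ivw(h, cfg$effects_model),
          mr_egger(h),
          mr_weighted_median(h, n_boot = cfg$n_boot, seed = seed))
        uni_rows[[length(uni_rows) + 1L]] <-
          tidy_estimates(ests, exposure = exp_lab, outcome = out_lab)
      }
    }
  }
  if (length(uni_rows)) {
    results$univariable <- do.call(rbind, uni_rows)
    rownames(results$univariable) <- NULL
    emit(results$univariable, "univariable_estimates.tsv")
  }

  ## ---- multivariable ---------------------------------------------------
  if (isTRUE(cfg$analyses$multivariable) && length(exposures) >= 2) {
    mv_rows <- list(); dec_rows <- list()
    focal <- cfg$focal_exposure %||% names(exposures)[1]
    for (out_lab in names(outcomes)) {
      cand_multi <- lapply(exposures, function(x)
        x[x$variant_id %in% kept_multi, ])
      hm <- harmonize_multi(cand_multi, outcomes[[out_lab]], band)
      say("stage mvmr[%s]: %d variants across %d exposures",
          out_lab, nrow(hm), length(exposures))
      mv_ivw <- mvmr_ivw(hm)
      mv_egg <- mvmr_egger(hm, focal_exposure = focal)
      mv_rows[[length(mv_rows) + 1L]] <-
        tidy_estimates(list(mv_ivw, mv_egg), outcome = out_lab)

      if (isTRUE(cfg$analyses$univariable)) {
        tot <- results$univariable
        tot <- tot[tot$exposure == focal & tot$outcome == out_lab &
                     tot$method %in% c("ivw_re", "ivw_fe"), ]
        if (nrow(tot) == 1) {
          total_est <- new_mr_estimate(tot$method, tot$beta, tot$se,
                                       tot$pval, tot$n_snps,
                                       exposure = focal, outcome = out_lab)
          dec <- decompose_effects(total_est, mv_ivw$estimates[[focal]])
          dec_rows[[length(dec_rows) + 1L]] <- data.frame(
            exposure = focal, outcome = out_lab,
            total = dec$total$theta, direct = dec$direct$theta,
            indirect = dec$indirect, se_indirect = dec$se_indirect,
            classification = dec$classification,
            stringsAsFactors = FALSE)
        }
      }
    }
    results$multivariable <- do.call(rbind, mv_rows)
    rownames(results$multivariable) <- NULL
    emit(results$multivariable, "mvmr_estimates.tsv")
    if (length(dec_rows)) {
      results$decomposition <- do.call(rbind, dec_rows)
      emit(results$decomposition, "decomposition.tsv")
    }

    # FDR over the multivariable slope p-values (the declared family)
    fam <- results$multivariable[results$multivariable$method == "mvmr_ivw", ]
    if (nrow(fam) >= 1) {
      fdr <- cbind(fam[c("exposure", "outcome", "method")],
                   bh_fdr(fam$pval, cfg$fdr_q))
      results$fdr <- fdr
      emit(fdr, "fdr.tsv")
      say("stage fdr: %d/%d pass at q = %g", sum(fdr$pass), nrow(fdr),
          cfg$fdr_q)
    }
  }

  ## ---- reverse GRS -----------------------------------------------------
  if (isTRUE(cfg$analyses$reverse)) {
    if (!is.null(cfg$reverse$cohort)) {
      cohort <- read_cohort_tsv(cfg$reverse$cohort)
      instr <- utils::read.table(cfg$reverse$instruments, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    } else if (!is.null(sim)) {
      instr <- sim_instrument_set(sim)
      cohort <- simulate_cohort(sim$config, instr)
    } else {
      stop(config_error("reverse analysis needs a `reverse` config block ",
                        "or simulated data"))
    }
    g <- grs_regression(cohort, instr)
    results$reverse <- data.frame(
      phenotype = g$phenotype, beta = g$beta, se = g$se,
      ci_low = g$ci_low, ci_high = g$ci_high, pval = g$pval,
      n = g$n, n_snps = g$n_snps, stringsAsFactors = FALSE)
    emit(results$reverse, "reverse_grs.tsv")
    say("stage reverse: beta %.4f per 1-SD GRS (p = %.3g)", g$beta, g$pval)
  }

  ## ---- intervention ----------------------------------------------------
  if (isTRUE(cfg$analyses$intervention)) {
    iv <- cfg$intervention
    if (is.null(iv))
      stop(config_error("intervention analysis needs an `intervention` ",
                        "config block"))
    res <- intervention_model(unlist(iv$proportions), iv$rr,
                              iv$baseline_prevalence, iv$shift)
    results$intervention <- data.frame(
      baseline_prevalence_pct = res$baseline_prevalence_pct,
      post_prevalence_pct = res$post_prevalence_pct,
      percent_reduction = res$percent_reduction,
      percent_reduction_exact = res$percent_reduction_exact)
    emit(results$intervention, "intervention.tsv")
    emit(res$category_table, "intervention_categories.tsv")
    say("stage intervention: prevalence %.2f%% -> %.2f%%",
        res$baseline_prevalence_pct, res$post_prevalence_pct)
  }

  ## ---- forest table and audit ------------------------------------------
  all_est <- rbind(results$univariable, results$multivariable)
  if (!is.null(all_est) && nrow(all_est)) {
    results$forest <- make_forest_table(all_est)
    emit(results$forest, "forest_table.tsv")
  }
  if (length(drop_rows)) {
    results$drops <- do.call(rbind, drop_rows)
    emit(results$drops, "harmonisation_drops.tsv")
  }
  writeLines(c(sprintf("config_hash\t%s", hash),
               sprintf("seed\t%d", seed), log_lines),
             file.path(out_dir, "run.log"))

  attr(results, "out_dir") <- out_dir
  attr(results, "config_hash") <- hash
  invisible(results)
}
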