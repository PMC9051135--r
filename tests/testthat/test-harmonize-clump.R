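# allele harmonisation and LD clumping

test_that("aligned and swapped codings are handled per the alignment rules", {
  ex <- sumstats_table(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                       beta = c(0.10, 0.10))
  ou <- sumstats_table(c("rs1", "rs2"), c("A", "G"), c("G", "A"),
                       beta = c(0.05, 0.05), eaf = c(0.3, 0.3))
  h <- harmonize(ex, ou)
  expect_equal(h$action, c("aligned", "flipped"))
  expect_equal(h$beta_y, c(0.05, -0.05))
  expect_equal(h$eaf_outcome, c(0.3, 0.7))
})

test_that("opposite-strand non-palindromic codings are resolved", {
  ex <- sumstats_table(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                       beta = c(0.1, 0.1))
  # rs1 reported as T/C (complement of A/G), rs2 as C/T (complement swap)
  ou <- sumstats_table(c("rs1", "rs2"), c("T", "C"), c("C", "T"),
                       beta = c(0.05, 0.05), eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_equal(h$action, c("aligned", "flipped"))
  expect_equal(h$beta_y, c(0.05, -0.05))
})

test_that("irreconcilable alleles and missing variants drop with reasons", {
  ex <- sumstats_table(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                       c("G", "C", "G"), beta = c(0.1, 0.1, 0.1))
  ou <- sumstats_table(c("rs1", "rs2", "rs4"), c("A", "A", "A"),
                       c("G", "G", "G"), beta = c(0.05, 0.05, 0.05))
  h <- harmonize(ex, ou)
  expect_equal(h$variant_id, "rs1")
  drops <- attr(h, "drops")
  expect_setequal(drops$reason[drops$variant_id == "rs2"], "allele_mismatch")
  expect_setequal(drops$reason[drops$variant_id == "rs3"], "absent_outcome")
  expect_setequal(drops$reason[drops$variant_id == "rs4"], "absent_exposure")
  # empty intersection is a hard error
  expect_error(
    harmonize(sumstats_table("rs9", "A", "G", 0.1),
              sumstats_table("rs8", "A", "G", 0.1)),
    "no variants shared")
})

test_that("palindromic band rule matches its enumeration over an EAF grid", {
  band <- c(0.42, 0.58)
  grid <- seq(0.01, 0.99, by = 0.07)
  grid <- c(grid, 0.50)  # the exactly-ambiguous point
  for (f_x in grid) for (f_y in c(0.05, 0.30, 0.50, 0.70, 0.95)) {
    ex <- sumstats_table(c("rs1", "rsf"), c("A", "A"), c("T", "G"),
                         beta = c(0.1, 0.1), eaf = c(f_x, 0.3))
    ou <- sumstats_table(c("rs1", "rsf"), c("A", "A"), c("T", "G"),
                         beta = c(0.05, 0.05), eaf = c(f_y, 0.3))
    h <- harmonize(ex, ou, band)
    in_band <- function(f) f >= band[1] & f <= band[2]
    if (in_band(f_x) || in_band(f_y)) {
      expect_false("rs1" %in% h$variant_id,
                   label = sprintf("drop at f_x=%.2f f_y=%.2f", f_x, f_y))
      expect_true("palindromic_ambiguous" %in% attr(h, "drops")$reason)
    } else {
      row <- h[h$variant_id == "rs1", ]
      expect_equal(nrow(row), 1)
      expected_beta <- if ((f_x < 0.5) != (f_y < 0.5)) -0.05 else 0.05
      expect_equal(row$beta_y, expected_beta,
                   label = sprintf("sign at f_x=%.2f f_y=%.2f", f_x, f_y))
    }
  }
})

test_that("palindromic variants with missing frequency are dropped", {
  ex <- sumstats_table(c("rs1", "rsf"), c("A", "A"), c("T", "G"),
                       beta = 0.1, eaf = c(NA, 0.3))
  ou <- sumstats_table(c("rs1", "rsf"), c("A", "A"), c("T", "G"),
                       beta = 0.05, eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_false("rs1" %in% h$variant_id)
  expect_true("palindromic_missing_eaf" %in% attr(h, "drops")$reason)
})

test_that("harmonisation is idempotent on its own output", {
  sim <- simulate_summary_pair(sim_config(
    n_instruments = c(a = 60), true_effects = c(a = 0.5),
    frac_palindromic = 0.2, frac_allele_swapped = 0.3, seed = 13))
  h1 <- harmonize(sim$exposures$a, sim$outcome)
  # rebuild tables from the harmonised (shared-coding) dataset
  ex2 <- sumstats_table(h1$variant_id, h1$effect_allele, h1$other_allele,
                        beta = h1$beta_x, se = h1$se_x, eaf = h1$eaf)
  ou2 <- sumstats_table(h1$variant_id, h1$effect_allele, h1$other_allele,
                        beta = h1$beta_y, se = h1$se_y, eaf = h1$eaf_outcome)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$variant_id, h1$variant_id)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$beta_x, h1$beta_x)
})

test_that("corrupt-then-harmonise restores uncorrupted outcome effects", {
  # at zero noise the uncorrupted outcome beta is the truth record's
  # beta_y_true; corruption must be exactly inverted for every
  # non-palindromic variant (and resolvable palindromic ones here, since
  # their frequencies are generated away from the ambiguity band)
  sim <- simulate_summary_pair(sim_config(
    n_instruments = c(a = 120), true_effects = c(a = 0.6),
    noise_scale = 0, frac_palindromic = 0.15, frac_allele_swapped = 0.4,
    seed = 29))
  expect_gt(sum(sim$truth$swapped), 0)
  h <- harmonize(sim$exposures$a, sim$outcome)
  truth <- sim$truth[match(h$variant_id, sim$truth$variant_id), ]
  nonpal <- !truth$palindromic
  expect_equal(sum(nonpal), sum(!sim$truth$palindromic))
  expect_equal(h$beta_y[nonpal], truth$beta_y_true[nonpal])
  # resolvable palindromic variants restored too
  expect_equal(h$beta_y, truth$beta_y_true)
})

test_that("multi-exposure harmonisation aligns every exposure to one coding", {
  sim <- simulate_summary_pair(sim_config(
    n_instruments = c(a = 40, b = 40),
    true_effects = c(a = 0.5, b = 0.1), noise_scale = 0,
    frac_palindromic = 0, frac_allele_swapped = 0.3, seed = 17))
  hm <- harmonize_multi(sim$exposures, sim$outcome)
  expect_s3_class(hm, "harmonized_data")
  expect_equal(attr(hm, "n_exposures"), 2L)
  truth <- sim$truth[match(hm$variant_id, sim$truth$variant_id), ]
  expect_equal(hm$beta_y, truth$beta_y_true)
  expect_equal(hm$`beta_x.a`, truth$gamma_a)
  expect_equal(hm$`beta_x.b`, truth$gamma_b)
})

test_that("clumping keeps independent sets and dominates by p-value", {
  # all independent -> all retained
  cand <- data.frame(variant_id = paste0("rs", 1:5),
                     pval = c(1e-9, 1e-8, 1e-7, 1e-10, 1e-6))
  expect_setequal(clump(cand, NULL), cand$variant_id)
  # r2 = 1 pair -> smaller p wins
  ld <- data.frame(variant_a = "rs1", variant_b = "rs2", r2 = 1.0)
  cand2 <- data.frame(variant_id = c("rs1", "rs2"), pval = c(1e-10, 1e-8))
  expect_equal(clump(cand2, ld), "rs1")
  # tie on p breaks lexicographically
  cand3 <- data.frame(variant_id = c("rsB", "rsA"), pval = c(1e-8, 1e-8))
  ld3 <- data.frame(variant_a = "rsA", variant_b = "rsB", r2 = 0.9)
  expect_equal(clump(cand3, ld3, 0.5), "rsA")
  expect_error(clump(cand, NULL, r2_threshold = 0), "0, 1")
  expect_error(clump(cand, NULL, r2_threshold = 1.5), "0, 1")
})

test_that("greedy clumping matches the brute-force oracle on dense instances", {
  for (seed in 1:20) {
    set.seed(seed)
    ids <- paste0("rs", sample(100:999, 8))
    pvals <- 10^runif(8, -12, -4)
    r2mat <- matrix(0, 8, 8, dimnames = list(ids, ids))
    for (i in 1:7) for (j in (i + 1):8)
      r2mat[i, j] <- r2mat[j, i] <- round(runif(1), 3)
    ld <- data.frame(
      variant_a = rep(ids, each = 8)[upper.tri(r2mat)],
      variant_b = rep(ids, times = 8)[upper.tri(r2mat)],
      r2 = r2mat[upper.tri(r2mat)])
    for (thr in c(0.001, 0.3, 0.8)) {
      got <- clump(data.frame(variant_id = ids, pval = pvals), ld, thr)
      want <- oracle_clump(ids, pvals, r2mat, thr)
      expect_identical(got, want, label = sprintf("seed %d thr %g", seed, thr))
      # post-hoc independence invariant
      expect_true(all(r2mat[got, got][upper.tri(diag(length(got)))] < thr))
    }
  }
})

test_that("aggregated clumping pools candidates under the min-p rule", {
  # disjoint independent sets retained in full
  s1 <- data.frame(variant_id = c("rs1", "rs2"), pval = c(1e-9, 1e-8))
  s2 <- data.frame(variant_id = c("rs3", "rs4"), pval = c(1e-7, 1e-6))
  expect_setequal(clump_multi(list(a = s1, b = s2), NULL),
                  c("rs1", "rs2", "rs3", "rs4"))
  # shared variant at r2 = 1 with a set-specific one: min-p decides
  childhood <- data.frame(variant_id = c("shared", "c1"),
                          pval = c(1e-12, 1e-8))
  adult <- data.frame(variant_id = c("shared", "a1"),
                      pval = c(1e-6, 1e-9))
  ld <- data.frame(variant_a = "shared", variant_b = "a1", r2 = 1.0)
  kept <- clump_multi(list(childhood = childhood, adult = adult), ld, 0.5)
  expect_true("shared" %in% kept)   # carries min p 1e-12, beats a1
  expect_false("a1" %in% kept)
  expect_true("c1" %in% kept)
  # single-exposure input reduces to plain clump
  expect_identical(as.character(clump_multi(list(a = childhood), ld, 0.5)),
                   clump(childhood, ld, 0.5))
})

test_that("summary-statistic reading rejects malformed records", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- sumstats_table(c("rs1", "rs2", "rs3"), c("A", "AT", "C"),
                        c("G", "A", "G"), beta = c(0.1, 0.2, 0.3))
  write_sumstats(tab, tf)
  expect_message(x <- read_sumstats(tf), "non-biallelic")
  expect_equal(x$variant_id, c("rs1", "rs3"))
  expect_equal(attr(x, "n_rejected"), 1L)

  dup <- sumstats_table(c("rs1", "rs1"), "A", "G", 0.1)
  expect_error(validate_sumstats(dup), "duplicate")
  bad_se <- sumstats_table("rs1", "A", "G", 0.1, se = 0)
  expect_error(validate_sumstats(bad_se), "positive")
  # warn-only beta/se vs p consistency check
  off <- sumstats_table("rs1", "A", "G", 0.1, se = 0.05)
  off$pval <- 1e-12
  expect_warning(validate_sumstats(off), "inconsistent")
})
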