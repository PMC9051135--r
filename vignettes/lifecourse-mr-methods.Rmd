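---
title: "Lifecourse Mendelian randomization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifecourse Mendelian randomization: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecourseMR)
```

## The scientific problem

Body size measured at different stages of the lifecourse — at birth, in
childhood, in adulthood — is genetically correlated, so an observed
association between childhood adiposity and a disease diagnosed early in
life may be a genuine childhood effect, a consequence of children who are
overweight remaining overweight into adulthood, or confounding from very
early growth. `lifecourseMR` implements the two-sample Mendelian
randomization (MR) machinery needed to separate these possibilities from
GWAS summary statistics alone:

* **univariable MR** estimates the *total* effect of an exposure on a
  disease outcome;
* **multivariable MR (MVMR)** with childhood body size, adult body size and
  optionally birthweight as simultaneous exposures estimates each
  exposure's *direct* effect conditional on the others;
* the difference (log scale) between total and direct is the *indirect*
  effect, mediated through the other exposures;
* **reverse-direction MR** (a weighted genetic risk score regressed against
  measured childhood BMI in an individual-level cohort) checks that the
  forward findings are not reverse causation;
* a **constant-relative-risk intervention model** translates a causal odds
  ratio into the population prevalence change achievable by shifting
  body-size category proportions.

Because the real inputs are large external GWAS summary files, the package
ships a synthetic-data generator that emulates their statistical structure,
so every stage of the pipeline is exercised by tests with known truth.

## Estimators

For variant $j$, let $\hat\beta_{Xjk}$ be its estimated effect on exposure
$k$ (standard error $\sigma_{Xjk}$) and $\hat\beta_{Yj}$ its estimated
effect on the outcome (log-odds, standard error $\sigma_{Yj}$). All
estimators use first-order inverse-variance weights
$w_j = \sigma_{Yj}^{-2}$.

**Wald ratio.** $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
$\mathrm{se} = \sigma_{Yj}/|\hat\beta_{Xj}|$ (no measurement error in the
exposure effect — the "NOME" approximation).

**IVW.** Origin-constrained weighted regression:
$\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} \big/ \sum_j w_j
\hat\beta_{Xj}^2$. Heterogeneity is Cochran's
$Q = \sum_j w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ and
$I^2 = \max\{0, (Q - \mathrm{df})/Q\}$. The default effects model is
*multiplicative random effects*: the fixed-effect standard error is
inflated by $\max\{1, \sqrt{Q/(J-1)}\}$, never deflated. The literature is
split on fixed vs multiplicative random effects and on normal vs t
reference distributions; we default to the conservative multiplicative
model with normal p-values and expose both choices in the configuration,
recording which was used.

**MR-Egger.** Variants are oriented so $\hat\beta_{Xj} \ge 0$ (negating
exposure and outcome effects jointly, so estimates are invariant to the
arbitrary allele orientation of the input), then outcome effects are
regressed on exposure effects *with* an intercept. A non-zero intercept
estimates the average directional pleiotropic effect; the slope remains a
consistent causal estimate when pleiotropy is independent of instrument
strength (the InSIDE assumption). Standard errors carry the same
multiplicative inflation with $J-2$ residual df, and p-values use
$t_{J-2}$.

**Weighted median.** Per-variant ratios $\hat\theta_j$ are combined at the
weighted 50th percentile (weights $(\hat\beta_{Xj}/\sigma_{Yj})^2$
normalised; linear interpolation of the midpoint cumulative-weight
function). The estimate is consistent when valid instruments carry at
least half the weight. Its standard error has no closed form, so we use a
seeded parametric bootstrap (default 1000 replicates; the seed is recorded
in the result) resampling both exposure and outcome effects from normals
with their standard errors.

**MVMR.** The outcome effects are regressed jointly on the $K$ exposures'
effect columns (no intercept for MVMR-IVW; with an intercept and
focal-exposure orientation for MVMR-Egger). Each slope is a direct effect
conditional on the other exposures. The exposure matrix is checked for
full column rank (hard error naming the collinear exposures) and a
condition number above 30 triggers a near-collinearity warning. Degrees of
freedom: $J-K$ (IVW) and $J-K-1$ (Egger); p-values use the corresponding t
distribution. This means the $K=1$ MVMR reduction reproduces univariable
IVW's estimate, SE and Q exactly, while p-values differ microscopically
(t vs normal) — a documented choice, not an accident.

**Decomposition.** indirect = total − direct on the log-odds scale, with
the approximate standard error $\sqrt{se_t^2 + se_d^2}$ that assumes
independence of the two estimates; the output carries an explicit
`se_is_approximate` flag. Classification is qualitative, mirroring how
lifecourse MR results are read: *direct* when the direct-effect CI
excludes zero; *mediated* when only the total-effect CI does; *none*
otherwise. No product-of-coefficients mediation model is attempted.

## Harmonisation and clumping

Exposure and outcome tables are matched on variant id only (rsID-keyed
summary statistics; no positional liftover). Alignment rules, in order:
identical coding kept; swapped alleles flip the outcome beta and reflect
its frequency; non-palindromic opposite-strand codings are resolved by
complementing; palindromic (A/T, C/G) variants are resolved from allele
frequency alone — both frequencies must fall outside the ambiguity band
(default **[0.42, 0.58]**, a conventional inference band; configurable)
and a disagreement in minor-allele side triggers sign correction.
Ambiguous or frequency-less palindromic variants and irreconcilable
allele pairs are dropped, each with a recorded reason written to the
per-run audit table. Indels and multi-allelic records are rejected at read
time with a logged count, since every estimator assumes biallelic coding.

Clumping is greedy: take the remaining variant with the smallest p-value
(ties broken lexicographically on id, for determinism), retain it, discard
everything with reference $r^2 \ge$ the threshold (default **0.001**)
against it. The pairwise $r^2$ table is taken as complete truth — pairs
absent from it count as independent; constructing $r^2$ from a reference
panel is out of scope. For MVMR the per-exposure candidate sets are pooled
(each variant carrying its minimum p-value across exposures) and clumped
as one set, so instruments are mutually independent across exposures, not
merely within each.

## The synthetic-data generator

`simulate_summary_pair()` works directly at the summary level, which is
the working assumption of every estimator used: per-SNP true exposure
effects $\gamma_{jk} \sim N(0, \sigma_\gamma^2)$ with configurable
correlation between the first two exposures' effect vectors; outcome
effects $\beta_{Yj} = \sum_k \theta_k\gamma_{jk} + \alpha_j + e_j$; and
standard errors $1/\sqrt{2f_j(1-f_j)n}$ for a study of size $n$ and
effect-allele frequency $f_j$. The corruption operators mimic real
harmonisation hazards: a configurable fraction of variants gets swapped
allele coding in the outcome table (beta negated, frequency reflected),
and a fraction is palindromic, with frequencies kept away from 0.5 by
default so harmonisation can resolve them (an `ambiguous_palindromes` flag
forces frequencies into [0.42, 0.58] to exercise the drop rule). A truth
record retains $\theta$, $\gamma_{jk}$, $\alpha_j$ and the corruption
flags for recovery tests. All draws derive from a single seeded stream, so
identical configurations reproduce byte-identical tables.

Parameter defaults state the emulated world: 280 + 515 instruments,
exposure GWAS of 453,169, outcome study of 173,981, effect-allele
frequencies in (0.05, 0.95), 10% palindromic variants, 20% swapped
codings, exposure correlation 0.3.

**Effect-size scale.** The per-SNP effect sd defaults to
$\sigma_\gamma = 0.25$. This is deliberately a *strong-instrument
stand-in*, not a claim about real per-SNP effect magnitudes (which are
unknown for these instruments and are anyway an order of magnitude
smaller): estimated exposure effects carry sampling noise, so IVW-type
estimators suffer errors-in-variables attenuation of order $1/\bar F$.
The recovery tests demand mean estimates within 4 Monte-Carlo SEs of
truth over 200 replicates of 795 instruments, a resolution of roughly
0.1% of the effect; the attenuation must therefore satisfy
$1/\bar F \lesssim \tfrac{1}{2}\times$ (4 MC SE)/$\theta$, which requires
$\sigma_\gamma \gtrsim 0.22$ ($\bar F \sim 10^4$) at these sample sizes.
At a realistic near-threshold scale ($\sigma_\gamma \approx 0.02$,
$\bar F \approx 80$) the attenuation is ~1.3% and the recovery criterion
is *not* attainable — a property of errors-in-variables regression, not
of the implementation. A green recovery test therefore establishes
correctness of the estimator algebra and calibration of its intervals in
the strong-instrument regime; it does not establish that weak-instrument
bias is absent from analyses of real data.

**Directional pleiotropy** is simulated relative to the exposure-raising
allele of the first exposure:
$\alpha_j = \mathrm{sign}(\gamma_{j1})\,N(\mu_\alpha, \sigma_\alpha)$.
With sign-symmetric instrument effects, an allele-coding-fixed directional
term would average out of the IVW numerator and bias nothing; tying the
sign to the exposure-raising orientation reproduces the textbook
behaviour — IVW biased in the pleiotropy direction, Egger intercept
non-zero, Egger slope consistent — while keeping $|\alpha_j|$ independent
of instrument strength, so InSIDE holds.

**What the generator does not emulate:** case-control ascertainment,
linkage disequilibrium *between* the exposure effects and pleiotropy, HLA
fine structure, winner's-curse selection of instruments, sample overlap
between exposure and outcome studies, and population stratification. Green
simulation tests say nothing about these hazards.

The individual-level path (`simulate_cohort()`) exists only for the
reverse-direction GRS analysis: genotypes are binomial(2, $f_j$), the
phenotype is `grs_effect` per SD of the true weighted score plus small
age/sex effects (ages uniform on 8.9–11.5 years, emulating a childhood
clinic measurement) and Gaussian noise.

## The intervention model

Given ordered category proportions $p_i$ ($i = 0 \dots C-1$), a relative
risk $RR$ per one-category increase, and overall prevalence $P$, the
bottom-category risk solves $P = r\sum_i p_i RR^{\,i}$. The modelled
intervention moves a fraction of the population down from the top category
into the middle and an equal fraction from the middle to the bottom, then
recomputes prevalence with the same per-category risks (odds ratios
treated as relative risks — adequate for a rare outcome at 0.5%
prevalence). For the reproduced three-category scenario (0.33 / 0.511 /
0.159, where the middle proportion is one minus the two published outer
proportions; RR 2.64; shift 0.10) the post-shift prevalence is 0.39% when
rounded to two decimals. The headline percent reduction is computed from
the *rounded* prevalences (0.50% → 0.39% gives exactly 22%), matching how
such figures are typically printed; the full-precision reduction (21.42%)
is always reported alongside, and the small discrepancy is documented
rather than resolved, since whether the published outer proportions are
themselves rounded is unknown.

## Multiple testing and the FDR family

`bh_fdr()` is the standard Benjamini–Hochberg step-up adjustment. In the
pipeline the declared family is the set of MVMR-IVW slope p-values across
the disease panel (for the emulated analysis, 7 diseases × 2 exposures =
m = 14), thresholded at q = 0.05 by default; both family and threshold are
configurable.

## Numerical and degenerate-input choices

* WLS fits use the weighted normal equations (`solve` on $X^TWX$);
  datasets here are tiny (hundreds of rows, ≤ 4 columns), so no QR
  machinery is needed, and the oracle tests pin the results to an
  independent `lm()` route at 1e-10.
* Generated p-values are floored at 1e-300 so strong instruments cannot
  underflow to an invalid exact zero.
* Weighted-median edge cases: zero exposure effects are excluded with a
  warning (error if fewer than 3 usable variants remain); a cumulative
  weight already past 0.5 at the first ratio returns that ratio.
* $I^2$ is floored at zero when $Q < \mathrm{df}$.
* Clumping asserts post-hoc that no retained pair reaches the threshold;
  ties on p-value are broken lexicographically.
* The pipeline stamps every output table with a 32-bit FNV-1a hash of the
  configuration and the seed; reruns with the same configuration are
  byte-identical.
* Configuration files are JSON (the environment guarantees `jsonlite`;
  no YAML parser is assumed).

## Known limitations

* No Steiger filtering, outlier-pruned IVW, mode-based estimators or
  conditional instrument-strength (Q_x) statistics.
* The indirect-effect SE assumes independence of total and direct
  estimates, which share data; it is labelled approximate and should not
  be used for formal inference on mediation.
* The GRS path assumes complete additive dosages; no missingness handling.
* The LD table is trusted as given; there is no reference-panel
  computation or proxy-variant lookup.
* Estimates for binary outcomes are on the log-odds scale throughout;
  the OR ≈ RR approximation in the intervention model degrades for common
  outcomes.
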