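Package: lifecourseMR
Title: Lifecourse Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) analysis of exposures
    measured at different stages of the lifecourse, from raw GWAS
    summary-statistic tables through allele harmonisation and LD clumping to
    univariable (IVW, MR-Egger, weighted median) and multivariable MR
    estimation of total, direct and indirect effects on disease risk.
    Includes reverse-direction genetic risk score regression,
    Benjamini-Hochberg false discovery rate control across a disease panel,
    and a constant-relative-risk category-shift intervention model for
    population disease prevalence. A synthetic GWAS generator emulates the
    statistical structure of two-sample summary data (per-SNP effects,
    sampling noise, directional pleiotropy, palindromic and swapped allele
    codings, block LD) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
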