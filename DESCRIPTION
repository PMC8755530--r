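Package: summr
Title: Two-Sample Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomisation (MR)
    from GWAS summary statistics: instrument selection (significance
    thresholds, greedy LD clumping, F-statistic screening), allele
    harmonisation with palindromic-variant handling and local proxy lookup,
    five causal-effect estimators (Wald ratio, inverse-variance weighting
    with fixed or multiplicative random effects, weighted median, MR-Egger,
    and the simple-model robust adjusted profile score), heterogeneity
    statistics, and a closed-form power approximation for binary outcomes.
    Includes a synthetic two-sample GWAS generator with configurable
    pleiotropy, InSIDE violation, and record corruption (allele swaps,
    strand flips, palindromic conversion, missing allele frequencies) for
    end-to-end validation, applied to the question of whether circulating
    interleukin-18 affects COVID-19 susceptibility and severity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
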