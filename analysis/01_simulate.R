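#!/usr/bin/env Rscript
# Build the synthetic two-sample study the rest of the workflow analyses:
# one exposure GWAS (a cytokine measured in 3,636 people, the scale of
# the interleukin-18 GWAS) and three binary COVID-19 outcome GWAS at the
# case/non-case counts of the HGI round-6 meta-analysis (any,
# hospitalised, very severe), with a causal log-OR of log(0.96) per SD of
# exposure and no pleiotropy. Outcome records are then corrupted with
# allele swaps, strand flips, palindromic conversions and masked EAFs to
# give harmonisation real work, and the top instrument is removed from
# the very-severe panel to emulate instrument attrition.

library(summr)

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L

severities <- list(
  any = list(n_cases = 112612, n_controls = 2474079),
  hospitalised = list(n_cases = 24274, n_controls = 2061529),
  severe = list(n_cases = 8779, n_controls = 1001875)
)

base_cfg <- function(sev) {
  n <- sev$n_cases + sev$n_controls
  # gamma_sd = 0.07 puts selection in the regime of a small cytokine
  # GWAS: a handful of genome-wide-significant instruments jointly
  # explaining a few percent of the exposure variance.
  sim_config(
    j_variants = 60, n_exposure = 3636, n_outcome = n,
    true_beta = log(0.96), gamma_sd = 0.07,
    case_fraction = sev$n_cases / n, ld_block_size = 3,
    palindromic_fraction = 0.10, allele_swap_fraction = 0.15,
    strand_flip_fraction = 0.15, missing_eaf_fraction = 0.05,
    seed = seed
  )
}

# The exposure draws precede the outcome draws in the generator's RNG
# order, so the three severity runs share one exposure panel exactly.
exposure <- NULL
panels <- list()
for (name in names(severities)) {
  cfg <- base_cfg(severities[[name]])
  dat <- generate_two_sample(cfg)
  crp <- corrupt_for_harmonisation(dat$outcome, cfg, exposure = dat$exposure)
  exposure <- crp$exposure
  panels[[name]] <- crp$outcome
  jsonlite::write_json(dat$truth, file.path(out_dir, paste0("truth_", name, ".json")),
                       dataframe = "rows", digits = 10)
}

# Instrument attrition: remove the strongest exposure variant from the
# very-severe outcome, as happens when a smaller GWAS lacks a variant.
top_variant <- exposure$records$variant_id[which.min(exposure$records$pval)]
panels$severe$records <-
  panels$severe$records[panels$severe$records$variant_id != top_variant, ]
cat(sprintf("removed %s from the very-severe outcome panel\n", top_variant))

cfg_any <- base_cfg(severities$any)
lp <- generate_ld_and_proxies(exposure, cfg_any)

# Instrument strength for the power block, computed from the uncorrupted
# exposure panel (the corrupted one has masked EAFs): the variance
# explained by the clumped genome-wide-significant set. In a real
# analysis this constant comes from the source GWAS publication.
dat_clean <- generate_two_sample(cfg_any)
inst_clean <- clump(dat_clean$exposure, lp$ld, selection_params())
r2_instruments <- inst_clean$r2_total
cat(sprintf("instrument r2 on the exposure (uncorrupted panel): %.3f\n",
            r2_instruments))

write_panel(exposure, file.path(out_dir, "exposure.tsv"))
for (name in names(panels)) {
  write_panel(panels[[name]], file.path(out_dir, paste0("outcome_", name, ".tsv")))
}
write.table(lp$ld$pairs, file.path(out_dir, "ld.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(lp$proxies, file.path(out_dir, "proxies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

yaml::write_yaml(list(
  exposure = list(path = "exposure.tsv", trait_type = "continuous",
                  trait_id = "cytokine"),
  outcomes = list(
    any = list(path = "outcome_any.tsv", trait_type = "binary"),
    hospitalised = list(path = "outcome_hospitalised.tsv",
                        trait_type = "binary"),
    severe = list(path = "outcome_severe.tsv", trait_type = "binary")
  ),
  ld = "ld.tsv",
  proxies = "proxies.tsv",
  selection = list(p_threshold = 5e-8, clump_r2 = 0.001, f_min = 10,
                   proxy_r2_min = 0.8),
  liberal = list(p_threshold = 5e-6, clump_r2 = 0.001, f_min = 10,
                 proxy_r2_min = 0.8),
  estimator = list(bootstrap_reps = 1000, seed = seed,
                   effects_mode = "auto"),
  power = list(r2_override = r2_instruments, alpha = 0.05,
               target_power = 0.8)
), file.path(out_dir, "config.yaml"))

cat(sprintf("wrote exposure (%d variants) and %d outcome panels to %s\n",
            nrow(exposure$records), length(panels), out_dir))
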