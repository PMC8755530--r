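rec1 <- function(id = "rs1", effect = "A", other = "G", beta = 0.1,
                 se = 0.02, eaf = 0.3) {
  data.frame(variant_id = id, effect_allele = effect, other_allele = other,
             beta = beta, se = se, eaf = eaf, stringsAsFactors = FALSE)
}

test_that("pairwise harmonisation applies the allele rules", {
  # Identical alleles: kept unchanged.
  h <- harmonise_pair(rec1(beta = 0.1), rec1(beta = -0.02, se = 0.01))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, -0.02)

  # Swapped alleles: outcome beta negated, EAF complemented.
  h <- harmonise_pair(rec1(beta = 0.1),
                      rec1(effect = "G", other = "A", beta = 0.02, eaf = 0.3))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.02)

  # Strand complement, same orientation: effects untouched.
  h <- harmonise_pair(rec1(effect = "A", other = "G"),
                      rec1(effect = "T", other = "C", beta = 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_outcome, 0.05)

  # Strand complement plus swap: negated.
  h <- harmonise_pair(rec1(effect = "A", other = "G"),
                      rec1(effect = "C", other = "T", beta = 0.05))
  expect_equal(h$action, "strand_flipped")
  expect_equal(h$beta_outcome, -0.05)

  # Irreconcilable alleles.
  h <- harmonise_pair(rec1(effect = "A", other = "G"),
                      rec1(effect = "A", other = "C"))
  expect_equal(h$action, "dropped_allele_mismatch")

  expect_error(harmonise_pair(rec1(id = "rs1"), rec1(id = "rs2")),
               "mismatch")
})

test_that("palindromic variants follow the EAF rules", {
  pal_exp <- rec1(effect = "A", other = "T", eaf = NA)
  pal_out <- rec1(effect = "A", other = "T", beta = 0.05, eaf = 0.2)
  # Missing exposure EAF: dropped.
  expect_equal(harmonise_pair(pal_exp, pal_out)$action, "dropped_palindromic")
  # Informative frequencies, same minor allele: kept as-is.
  h <- harmonise_pair(rec1(effect = "A", other = "T", eaf = 0.25), pal_out)
  expect_equal(h$action, "kept")
  expect_equal(h$beta_outcome, 0.05)
  # Frequencies disagree: orientation flipped.
  h <- harmonise_pair(rec1(effect = "A", other = "T", eaf = 0.75), pal_out)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_outcome, -0.05)
  # Near-0.5 frequency is ambiguous: dropped.
  h <- harmonise_pair(rec1(effect = "A", other = "T", eaf = 0.45), pal_out)
  expect_equal(h$action, "dropped_palindromic")
})

test_that("harmonisation is idempotent and double swap is the identity", {
  e <- rec1(beta = 0.12, eaf = 0.3)
  o <- rec1(beta = -0.03, se = 0.01, eaf = 0.31)
  h1 <- harmonise_pair(e, o)
  # Re-harmonising the aligned outcome changes nothing.
  o_aligned <- rec1(beta = h1$beta_outcome, se = h1$se_outcome, eaf = 0.31)
  h2 <- harmonise_pair(e, o_aligned)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$action, "kept")

  swap_once <- rec1(effect = "G", other = "A", beta = 0.03, eaf = 0.69)
  h_swap <- harmonise_pair(e, swap_once)
  expect_equal(h_swap$beta_outcome, -0.03)
  # Swapping twice returns the original record.
  twice <- rec1(effect = "A", other = "G", beta = -0.03, eaf = 0.31)
  expect_equal(harmonise_pair(e, twice)$beta_outcome,
               harmonise_pair(e, o)$beta_outcome)
})

test_that("Wald ratios are invariant under allele-swap corruption", {
  cfg <- sim_config(j_variants = 10, allele_swap_fraction = 1, seed = 31)
  dat <- generate_two_sample(cfg)
  hs_clean <- as_harmonised(dat$exposure, dat$outcome)
  corrupted <- corrupt_for_harmonisation(dat$outcome, cfg)$outcome
  params <- selection_params(p_threshold = 1 - 1e-12, f_min = 0)
  inst <- clump(dat$exposure, NULL, params)
  hs_fixed <- harmonise_panels(inst, corrupted, params = params)
  k_clean <- hs_clean[order(hs_clean$variant_id), ]
  k_fixed <- hs_fixed[order(hs_fixed$variant_id), ]
  expect_equal(k_fixed$beta_outcome / k_fixed$beta_exposure,
               k_clean$beta_outcome / k_clean$beta_exposure)
})

test_that("an instrument missing from the outcome is proxied or dropped", {
  exp_panel <- trait_panel(make_records(4), "il18", "continuous")
  inst <- clump(exp_panel, NULL, selection_params())
  # Outcome lacks rs4; its best correlate is below the r2 cut-off.
  out_panel <- trait_panel(make_records(3), "severe", "continuous")
  proxies <- data.frame(variant_id = "rs4", proxy_id = "rs9", r2 = 0.65)
  h <- harmonise_panels(inst, out_panel, proxies)
  expect_equal(nrow(h), 4L)
  expect_equal(sum(!startsWith(h$action, "dropped")), 3L)
  expect_equal(h$action[h$variant_id == "rs4"], "dropped_missing")

  # With a qualifying proxy present in the outcome, the proxy's effects
  # are adopted for the index variant.
  out5 <- make_records(4, ids = c("rs1", "rs2", "rs3", "rsProxy"))
  out_panel2 <- trait_panel(out5, "hosp", "continuous")
  proxies2 <- data.frame(variant_id = "rs4", proxy_id = "rsProxy", r2 = 0.92)
  h2 <- harmonise_panels(inst, out_panel2, proxies2)
  row <- h2[h2$variant_id == "rs4", ]
  expect_equal(row$action, "kept")
  expect_equal(row$outcome_variant, "rsProxy")
  expect_equal(row$proxy_r2, 0.92)
  expect_equal(row$beta_outcome, out5$beta[out5$variant_id == "rsProxy"])

  # All instruments present with identical alleles: everything kept.
  h3 <- harmonise_panels(inst, trait_panel(make_records(4), "any",
                                           "continuous"))
  expect_true(all(h3$action == "kept"))
})

test_that("harmonisation undoes the full corruption battery", {
  cfg <- sim_config(j_variants = 80, palindromic_fraction = 0.3,
                    allele_swap_fraction = 0.4, strand_flip_fraction = 0.4,
                    missing_eaf_fraction = 0.15, seed = 61)
  dat <- generate_two_sample(cfg)
  crp <- corrupt_for_harmonisation(dat$outcome, cfg, exposure = dat$exposure)
  params <- selection_params(p_threshold = 1 - 1e-12, f_min = 0)
  inst <- clump(crp$exposure, NULL, params)
  h <- harmonise_panels(inst, crp$outcome, params = params)
  orig <- dat$outcome$records

  kept <- h[!startsWith(h$action, "dropped"), ]
  expect_gt(nrow(kept), 0)
  i <- match(kept$variant_id, orig$variant_id)
  expect_equal(kept$beta_outcome, orig$beta[i])

  # Every drop is a palindromic ambiguity the manifest explains: EAF
  # masked, or a frequency too close to 0.5 to orient.
  dropped <- h[startsWith(h$action, "dropped"), ]
  if (nrow(dropped) > 0) {
    m <- crp$manifest[match(dropped$variant_id, crp$manifest$variant_id), ]
    expect_true(all(m$palindromic))
    expect_equal(dropped$action, rep("dropped_palindromic", nrow(dropped)))
  }
})
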