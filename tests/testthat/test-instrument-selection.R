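test_that("F-statistic is the squared z-score", {
  expect_equal(f_statistic(0.2, 0.04), 25)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_equal(f_statistic(list(beta = c(0.1, -0.1), se = c(0.02, 0.05))),
               c(25, 4))
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("variance explained follows 2p(1-p)beta^2 and matches an
           individual-level simulation", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_error(variance_explained(0.1, NA), "missing")

  # Oracle: simulate genotypes and a standardised exposure; the squared
  # correlation between the allele score and the exposure should equal the
  # summed per-variant formula within simulation error.
  withr_seed(99, {
    n <- 1e5
    p <- c(0.2, 0.35, 0.5)
    gamma <- c(0.15, -0.1, 0.08)
    g <- sapply(p, function(pp) rbinom(n, 2, pp))
    score <- drop(g %*% gamma)
    resid_var <- 1 - sum(gamma^2 * 2 * p * (1 - p))
    x <- score + rnorm(n, 0, sqrt(resid_var))
    sim_r2 <- cor(score, x)^2
  })
  expect_equal(sum(variance_explained(gamma, p)), sim_r2, tolerance = 0.01)
})

test_that("clumping applies thresholds, greedy pruning and determinism", {
  rec <- make_records(6, beta = c(0.25, 0.22, 0.2, 0.18, 0.05, 0.16),
                      se = rep(0.02, 6))
  rec$eaf <- rep(0.3, 6)
  panel <- trait_panel(rec, "x", "continuous")
  # rs5 fails both p-threshold and F >= 10 ((0.05/0.02)^2 = 6.25).
  inst <- clump(panel, NULL, selection_params())
  expect_false("rs5" %in% inst$variants$variant_id)
  expect_equal(nrow(inst$variants), 5L)
  expect_true(all(inst$per_variant_f >= 10))
  expect_equal(unname(inst$per_variant_f),
               (inst$variants$beta / inst$variants$se)^2)
  expect_equal(inst$r2_total,
               sum(variance_explained(inst$variants$beta, inst$variants$eaf)))

  # Four mutually uncorrelated genome-wide-significant variants all
  # survive (the four-instrument pattern of a well-instrumented exposure).
  quad <- trait_panel(make_records(4), "x", "continuous")
  expect_equal(nrow(clump(quad, NULL)$variants), 4L)

  expect_error(clump(panel, NULL, selection_params(p_threshold = 1e-300)),
               "no instruments")
})

test_that("greedy clumping matches brute-force enumeration on small instances", {
  # Oracle: an explicit, independently written pass over candidates sorted
  # by (p, chr, pos, id), removing neighbours at or above the r2 cut.
  brute <- function(rec, ld_pairs, params) {
    f <- (rec$beta / rec$se)^2
    cand <- rec[rec$pval < params$p_threshold & f >= params$f_min, ]
    cand <- cand[order(cand$pval, cand$chromosome, cand$position,
                       cand$variant_id), ]
    get_r2 <- function(a, b) {
      if (a == b) return(1)
      hit <- (ld_pairs$variant_a == a & ld_pairs$variant_b == b) |
        (ld_pairs$variant_a == b & ld_pairs$variant_b == a)
      if (any(hit)) ld_pairs$r2[hit][1] else 0
    }
    kept <- character(0)
    pool <- cand$variant_id
    while (length(pool)) {
      lead <- pool[1]
      kept <- c(kept, lead)
      pool <- Filter(function(v) get_r2(lead, v) < params$clump_r2, pool[-1])
    }
    kept
  }
  params <- selection_params(p_threshold = 1e-4, clump_r2 = 0.1)
  for (seed in 1:20) {
    withr_seed(seed, {
      j <- sample(2:6, 1)
      rec <- make_records(j, beta = runif(j, 0, 0.3), se = rep(0.02, j))
      npairs <- sample(0:3, 1)
      ld_pairs <- data.frame(variant_a = character(0),
                             variant_b = character(0), r2 = numeric(0))
      if (npairs > 0 && j >= 2) {
        cmb <- combn(rec$variant_id, 2)
        pick <- sample(ncol(cmb), min(npairs, ncol(cmb)))
        ld_pairs <- data.frame(variant_a = cmb[1, pick],
                               variant_b = cmb[2, pick],
                               r2 = runif(length(pick)))
      }
    })
    panel <- trait_panel(rec, "x", "continuous")
    got <- tryCatch(
      clump(panel, ld_table(ld_pairs), params)$variants$variant_id,
      error = function(e) character(0)
    )
    expect_equal(got, brute(rec, ld_pairs, params),
                 info = sprintf("seed %d", seed))
  }
})

test_that("clumping is row-order invariant and monotone in the p-threshold", {
  cfg <- sim_config(j_variants = 24, ld_block_size = 3, seed = 77,
                    gamma_sd = 0.2)
  dat <- generate_two_sample(cfg)
  lp <- generate_ld_and_proxies(dat$exposure, cfg)
  params <- selection_params(p_threshold = 1e-6, clump_r2 = 0.3)
  base <- clump(dat$exposure, lp$ld, params)

  shuffled <- dat$exposure
  withr_seed(1, shuffled$records <- shuffled$records[sample(24), ])
  expect_equal(clump(shuffled, lp$ld, params)$variants$variant_id,
               base$variants$variant_id)

  # All retained pairs are below the r2 cut.
  ids <- base$variants$variant_id
  if (length(ids) > 1) {
    cmb <- combn(ids, 2)
    expect_true(all(ld_r2(lp$ld, cmb[1, ], cmb[2, ]) < params$clump_r2))
  }
  # Tightening the threshold never adds instruments.
  tight <- clump(dat$exposure, lp$ld,
                 selection_params(p_threshold = 1e-10, clump_r2 = 0.3))
  expect_true(all(tight$variants$variant_id %in% ids))
})

test_that("proxy lookup prefers the variant itself, then the best proxy", {
  out_rec <- make_records(3, ids = c("rs1", "rsP1", "rsP2"))
  outcome <- trait_panel(out_rec, "y", "continuous")
  proxies <- data.frame(
    variant_id = c("rs9", "rs9", "rs9"),
    proxy_id = c("rsP1", "rsP2", "rsP3"),
    r2 = c(0.85, 0.9, 0.95)
  )
  # Present in outcome: returned unchanged, no proxy attribute.
  hit <- find_proxy("rs1", outcome, proxies)
  expect_equal(hit$variant_id, "rs1")
  expect_null(attr(hit, "proxy"))
  # Absent: the highest-r2 proxy that is present wins (rsP3 is absent).
  px <- find_proxy("rs9", outcome, proxies)
  expect_equal(px$variant_id, "rsP2")
  expect_equal(attr(px, "proxy")$r2, 0.9)
  # A best correlate below the cut-off means the variant is dropped.
  weak <- data.frame(variant_id = "rs9", proxy_id = "rsP1", r2 = 0.65)
  expect_null(find_proxy("rs9", outcome, weak))
})
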