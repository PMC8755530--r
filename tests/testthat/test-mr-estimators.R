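test_that("Wald ratio divides effects and propagates the outcome SE", {
  h <- make_hs(0.5, 0.01, -0.02, 0.01)
  wr <- wald_ratio(h)
  expect_equal(wr$theta, -0.04)
  expect_equal(wr$se, 0.02)
  expect_equal(wald_ratio(make_hs(1, 0.01, 0.07, 0.02))$theta, 0.07)
  expect_error(wald_ratio(make_hs(0, 0.01, 0.07, 0.02)), "zero")
  # Second-order SE adds the exposure-uncertainty term.
  wr2 <- wald_ratio(h, second_order = TRUE)
  expect_equal(wr2$se, sqrt(0.01^2 / 0.5^2 + 0.02^2 * 0.01^2 / 0.5^4))
  expect_gt(wr2$se, wr$se)
})

test_that("IVW reduces to the Wald ratio for one variant and averages
           symmetric pairs", {
  h1 <- make_hs(0.4, 0.02, -0.016, 0.012)
  res <- mr_ivw(h1)
  wr <- wald_ratio(h1)
  expect_equal(res$beta, wr$theta)
  expect_equal(res$se, wr$se)
  expect_equal(res$effects, "fixed")

  # Equal weights, ratios 0.1 and 0.3: the estimate is their mean.
  h2 <- make_hs(c(0.2, 0.2), c(0.02, 0.02), c(0.02, 0.06), c(0.01, 0.01))
  expect_equal(mr_ivw(h2)$beta, 0.2)
})

test_that("IVW matches the weighted-least-squares-through-origin oracle", {
  for (seed in c(101, 102, 103)) {
    hs <- random_hs(7, seed)
    res <- mr_ivw(hs, effects_mode = "fixed")
    orc <- oracle_ivw_lm(hs)
    expect_equal(res$beta, orc$beta, tolerance = 1e-10)
    expect_equal(res$se, orc$se_fixed, tolerance = 1e-10)
    expect_equal(res$cochran_q, orc$q, tolerance = 1e-10)
  }
})

test_that("IVW dispersion rule: random effects only above 3 variants,
           and never below the fixed-effects SE", {
  hs3 <- random_hs(3, 7)
  hs4 <- random_hs(4, 7)
  expect_equal(mr_ivw(hs3)$effects, "fixed")
  expect_equal(mr_ivw(hs4)$effects, "multiplicative_random")
  for (seed in 1:10) {
    hs <- random_hs(6, 200 + seed)
    fixed <- mr_ivw(hs, "fixed")
    mre <- mr_ivw(hs, "multiplicative_random")
    expect_equal(mre$beta, fixed$beta)
    expect_gte(mre$se, fixed$se)
  }
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # Equal weights over ratios {-1, 0, 5}: the median is the middle ratio.
  hs <- make_hs(c(1, 1, 1), rep(0.01, 3), c(-1, 0, 5), rep(0.1, 3))
  expect_equal(mr_weighted_median(hs, 50, seed = 1)$beta, 0)
  # A variant carrying ~90% of the weight dominates the estimate.
  hs9 <- make_hs(c(1, 1, 1), rep(0.01, 3), c(0.5, -0.2, 0.1),
                 c(0.01, 0.35, 0.35))
  expect_equal(mr_weighted_median(hs9, 50, seed = 1)$beta, 0.5,
               tolerance = 0.02)
  expect_error(mr_weighted_median(make_hs(c(1, 1), c(0.01, 0.01),
                                          c(0, 0), c(0.1, 0.1)),
                                  50, seed = 1),
               "at least 3")
  expect_error(mr_weighted_median(hs, 50), "seed")
})

test_that("weighted median matches the CDF root-finding oracle", {
  for (seed in 301:308) {
    hs <- random_hs(7, seed)
    res <- mr_weighted_median(hs, 10, seed = 1)
    theta <- hs$beta_outcome / hs$beta_exposure
    w <- hs$beta_exposure^2 / hs$se_outcome^2
    expect_equal(res$beta, oracle_weighted_median(theta, w),
                 tolerance = 1e-6)
  }
})

test_that("weighted-median bootstrap SE is seeded and reproducible", {
  hs <- random_hs(9, 11)
  a <- mr_weighted_median(hs, 300, seed = 42)
  b <- mr_weighted_median(hs, 300, seed = 42)
  c <- mr_weighted_median(hs, 300, seed = 43)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
})

test_that("MR-Egger recovers an exact affine relation and matches lm", {
  gx <- c(0.05, 0.1, 0.2, 0.35)
  hs <- make_hs(gx, rep(0.01, 4), 0.05 + 0.3 * gx, rep(0.02, 4))
  res <- mr_egger(hs)
  expect_equal(res$beta, 0.3, tolerance = 1e-12)
  expect_equal(res$intercept, 0.05, tolerance = 1e-12)

  for (seed in c(401, 402, 403)) {
    hs <- random_hs(8, seed)
    hs$beta_exposure[1] <- -hs$beta_exposure[1]  # exercise orientation
    res <- mr_egger(hs)
    orc <- oracle_egger_lm(hs)
    expect_equal(res$beta, orc$beta, tolerance = 1e-10)
    expect_equal(res$se, orc$se, tolerance = 1e-10)
    expect_equal(res$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(res$intercept_se, orc$intercept_se, tolerance = 1e-10)
  }

  expect_error(mr_egger(make_hs(c(0.1, 0.1, -0.1), rep(0.01, 3),
                                c(0.01, 0.02, 0.03), rep(0.01, 3))),
               "collinear")
  expect_error(mr_egger(random_hs(2, 1)), "at least 3")
})

test_that("MR-RAPS reduces to IVW without exposure noise, is exact on
           proportional data, and matches the grid oracle", {
  hs <- random_hs(6, 501)
  hs$se_exposure <- rep(1e-12, 6)  # effectively no exposure noise
  expect_equal(mr_raps(hs)$beta, mr_ivw(hs, "fixed")$beta,
               tolerance = 1e-8)

  gx <- c(0.1, 0.15, 0.2, 0.3)
  exact <- make_hs(gx, rep(0.02, 4), -0.04 * gx, rep(0.01, 4))
  expect_equal(mr_raps(exact)$beta, -0.04, tolerance = 1e-8)

  for (seed in c(601, 602, 603)) {
    hs <- random_hs(7, seed)
    res <- mr_raps(hs)
    centre <- mr_ivw(hs, "fixed")$beta
    orc <- oracle_raps_grid(hs$beta_exposure, hs$se_exposure,
                            hs$beta_outcome, hs$se_outcome, centre)
    expect_equal(res$beta, orc, tolerance = 1e-6)
    expect_gt(res$se, 0)
  }
})

test_that("odds-scale conversion exponentiates binary results only", {
  null <- mr_result("IVW", 4L, beta = 0, se = 0.01)
  expect_equal(to_odds_scale(null, "o", "binary")$or_, 1)

  res <- mr_result("IVW", 4L, beta = -0.0408, se = 0.0133)
  row <- to_odds_scale(res, "covid_any", "binary")
  expect_equal(round(row$or_, 2), 0.96)
  expect_equal(round(row$ci_low, 2), 0.94)
  expect_equal(round(row$ci_high, 2), 0.99)
  expect_true(row$ci_low <= row$or_ && row$or_ <= row$ci_high)

  cont <- to_odds_scale(res, "children", "continuous")
  expect_true(is.na(cont$or_) && is.na(cont$ci_low))
  expect_equal(cont$beta, -0.0408)

  # Monotone: a larger beta maps to a larger OR.
  betas <- seq(-0.5, 0.5, by = 0.1)
  ors <- vapply(betas, function(b) {
    to_odds_scale(mr_result("IVW", 1L, b, 0.1), "o", "binary")$or_
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("estimators are scale/sign equivariant and order invariant", {
  run_all <- function(hs) {
    list(ivw = mr_ivw(hs)$beta,
         wm = mr_weighted_median(hs, 10, seed = 5)$beta,
         egger = mr_egger(hs)$beta,
         raps = mr_raps(hs)$beta)
  }
  for (seed in c(701, 702)) {
    hs <- random_hs(8, seed)
    base <- run_all(hs)

    # Rescaling the exposure by c divides every estimate by c.
    c0 <- 2.5
    scaled <- hs
    scaled$beta_exposure <- hs$beta_exposure * c0
    scaled$se_exposure <- hs$se_exposure * c0
    expect_equal(unlist(run_all(scaled)), unlist(base) / c0,
                 tolerance = 1e-6)

    # Negating the outcome negates every estimate.
    neg <- hs
    neg$beta_outcome <- -hs$beta_outcome
    expect_equal(unlist(run_all(neg)), -unlist(base), tolerance = 1e-6)

    # Variant order is irrelevant.
    withr_seed(1, perm <- sample(nrow(hs)))
    shuf <- hs[perm, ]
    expect_equal(unlist(run_all(shuf)), unlist(base), tolerance = 1e-6)
  }
})

test_that("with valid instruments all estimators agree within
           simulation error", {
  cfg <- sim_config(j_variants = 100, true_beta = -0.04, pleiotropy_sd = 0,
                    n_outcome = 5e6, seed = 88)
  dat <- generate_two_sample(cfg)
  hs <- as_harmonised(dat$exposure, dat$outcome)
  ivw <- mr_ivw(hs)
  wm <- mr_weighted_median(hs, 200, seed = 3)
  egg <- mr_egger(hs)
  raps <- mr_raps(hs)
  for (res in list(ivw, wm, egg, raps)) {
    expect_lt(abs(res$beta - (-0.04)), 3 * res$se)
  }
  expect_lt(abs(ivw$beta - raps$beta), 2 * ivw$se)
  expect_lt(abs(ivw$beta - wm$beta), 3 * ivw$se)
})

test_that("dropped variants never reach an estimator", {
  hs <- random_hs(5, 900)
  hs$action[1] <- "dropped_palindromic"
  hs$beta_outcome[1] <- NA
  res <- mr_ivw(hs)
  expect_equal(res$n_snp, 4L)
  expect_true(is.finite(res$beta))
  expect_error(wald_ratio(hs[1, ]), "dropped")
})
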