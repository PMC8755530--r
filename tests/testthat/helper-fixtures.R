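# Fixture builders and independent oracles shared across the suite.

# A harmonised data frame straight from effect arrays (all records kept).
make_hs <- function(bx, sx, by, sy, ids = sprintf("rs%d", seq_along(bx))) {
  h <- data.frame(
    variant_id = ids, effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    eaf_exposure = 0.3, action = "kept", outcome_variant = ids,
    proxy_r2 = NA_real_, stringsAsFactors = FALSE
  )
  class(h) <- c("harmonised", class(h))
  h
}

# Random but reproducible estimator fixture.
random_hs <- function(j, seed) {
  withr_seed(seed, {
    bx <- rnorm(j, 0.15, 0.05)
    sx <- runif(j, 0.01, 0.03)
    by <- 0.2 * bx + rnorm(j, 0, 0.02)
    sy <- runif(j, 0.01, 0.04)
  })
  make_hs(bx, sx, by, sy)
}

# Minimal local stand-in for withr::with_seed (withr not loaded in tests).
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

# A small association-record data frame with canonical columns.
make_records <- function(n = 4, eaf = seq(0.1, 0.4, length.out = n),
                         beta = seq(0.13, 0.25, length.out = n),
                         se = rep(0.02, n),
                         effect = rep("A", n), other = rep("G", n),
                         ids = sprintf("rs%d", seq_len(n))) {
  data.frame(
    variant_id = ids, chromosome = as.character(seq_len(n)),
    position = 1000L * seq_len(n), effect_allele = effect,
    other_allele = other, eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = 3636,
    stringsAsFactors = FALSE
  )
}

# --- Independent oracles -------------------------------------------------

# IVW via lm(): weighted regression of outcome on exposure effects through
# the origin, with the fixed-effects SE recovered by dividing out lm's
# residual scale.
oracle_ivw_lm <- function(hs) {
  k <- hs[hs$action == "kept", ]
  w <- 1 / k$se_outcome^2
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = k, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  list(beta = unname(coef(fit)[1]),
       se_fixed = unname(s$coefficients[1, 2] / sigma),
       q = sum(w * residuals(fit)^2))
}

# MR-Egger via lm(), with the multiplicative dispersion floored at 1.
oracle_egger_lm <- function(hs) {
  k <- hs[hs$action == "kept", ]
  flip <- k$beta_exposure < 0
  bx <- ifelse(flip, -k$beta_exposure, k$beta_exposure)
  by <- ifelse(flip, -k$beta_outcome, k$beta_outcome)
  w <- 1 / k$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  infl <- sqrt(max(1, sigma^2))
  list(beta = unname(coef(fit)["bx"]),
       se = unname(s$coefficients["bx", 2] / sigma * infl),
       intercept = unname(coef(fit)["(Intercept)"]),
       intercept_se = unname(s$coefficients["(Intercept)", 2] / sigma * infl))
}

# Weighted-median point estimate by root-finding on the interpolated
# weighted CDF (the forward map), rather than inverse interpolation.
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  cdf <- approxfun(theta, p, ties = "ordered")
  uniroot(function(x) cdf(x) - 0.5, range(theta), tol = 1e-12)$root
}

# Profile-likelihood maximiser by iterative grid refinement.
oracle_raps_grid <- function(bx, sx, by, sy, centre, halfwidth = 1) {
  ll <- function(b) {
    vapply(b, function(bb) {
      -0.5 * sum((by - bb * bx)^2 / (sy^2 + bb^2 * sx^2))
    }, numeric(1))
  }
  lo <- centre - halfwidth
  hi <- centre + halfwidth
  for (pass in 1:8) {
    grid <- seq(lo, hi, length.out = 2001)
    i <- which.max(ll(grid))
    step <- grid[2] - grid[1]
    lo <- grid[i] - 2 * step
    hi <- grid[i] + 2 * step
  }
  (lo + hi) / 2
}
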