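#' Construct an MR estimator result
#'
#' Container for one estimator's output: causal-effect estimate on the
#' outcome scale per SD of exposure (log-OR for binary outcomes), its
#' standard error, a normal-approximation 95% confidence interval and
#' two-sided p-value, and method-specific extras (Cochran's Q and the
#' multiplicative dispersion for IVW; intercept terms for MR-Egger).
#'
#' @param method Method label.
#' @param n_snp Number of variants used.
#' @param beta,se Estimate and standard error.
#' @param cochran_q,dispersion_phi Optional heterogeneity statistics.
#' @param intercept,intercept_se,intercept_p Optional Egger intercept.
#' @param effects Optional label of the variance model used (IVW).
#' @return An object of class `mr_result`.
#' @export
mr_result <- function(method, n_snp, beta, se, cochran_q = NA_real_,
                      dispersion_phi = NA_real_, intercept = NA_real_,
                      intercept_se = NA_real_, intercept_p = NA_real_,
                      effects = NA_character_) {
  if (!is.finite(beta) || !is.finite(se) || se <= 0) {
    stopf("%s: non-finite estimate or non-positive SE", method)
  }
  z <- z_ci()
  structure(
    list(method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
         ci_low = beta - z * se, ci_high = beta + z * se,
         pval = 2 * pnorm(-abs(beta / se)),
         cochran_q = cochran_q, dispersion_phi = dispersion_phi,
         intercept = intercept, intercept_se = intercept_se,
         intercept_p = intercept_p, effects = effects),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s (%d SNPs): beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (is.finite(x$intercept)) {
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

# Extract the kept (beta_x, se_x, beta_y, se_y) arrays, enforcing a
# minimum count.
estimator_inputs <- function(hs, min_snp, method) {
  k <- kept_records(hs)
  if (nrow(k) < min_snp) {
    stopf("%s requires at least %d usable variants, got %d",
          method, min_snp, nrow(k))
  }
  list(bx = k$beta_exposure, sx = k$se_exposure,
       by = k$beta_outcome, sy = k$se_outcome, n = nrow(k))
}

#' Per-variant Wald ratio
#'
#' The single-variant causal estimate: variant-outcome effect divided by
#' variant-exposure effect. The default standard error is the first-order
#' delta method, se_outcome / |beta_exposure|, consistent with the IVW
#' weights; `second_order = TRUE` adds the exposure-uncertainty term
#' sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4).
#'
#' @param h A one-row harmonised variant (action not dropped).
#' @param second_order Use the second-order delta-method SE (default
#'   `FALSE`).
#' @return List with `theta` and `se`.
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  h <- as.list(as.data.frame(h))
  if (startsWith(h$action %||% "kept", "dropped")) {
    stopf("wald_ratio: variant '%s' was dropped in harmonisation", h$variant_id)
  }
  bx <- h$beta_exposure
  if (is.na(bx) || bx == 0) {
    stopf("wald_ratio undefined: beta_exposure is zero for '%s'", h$variant_id)
  }
  theta <- h$beta_outcome / bx
  se <- if (second_order) {
    sqrt(h$se_outcome^2 / bx^2 + h$beta_outcome^2 * h$se_exposure^2 / bx^4)
  } else {
    h$se_outcome / abs(bx)
  }
  list(theta = theta, se = se)
}

#' Inverse-variance-weighted estimator
#'
#' Meta-analysis of the per-variant Wald ratios with weights
#' w_j = beta_exposure_j^2 / se_outcome_j^2 (the inverse first-order
#' variance), equivalent to weighted regression of outcome on exposure
#' effects through the origin. Heterogeneity is summarised by Cochran's
#' Q = sum w_j (theta_j - beta)^2 and the dispersion phi = Q/(J-1). Under
#' `effects_mode = "auto"` a multiplicative random-effects model is used
#' for more than 3 variants — the fixed-effects SE is inflated by
#' sqrt(max(1, phi)), never deflated — and fixed effects otherwise.
#'
#' @param hs Harmonised variants (dropped records are ignored).
#' @param effects_mode `"auto"`, `"fixed"`, or `"multiplicative_random"`.
#' @return An [mr_result()]; `effects` records the variance model used.
#' @export
mr_ivw <- function(hs, effects_mode = c("auto", "fixed", "multiplicative_random")) {
  effects_mode <- match.arg(effects_mode)
  d <- estimator_inputs(hs, 1L, "IVW")
  w <- d$bx^2 / d$sy^2
  theta <- d$by / d$bx
  beta <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - beta)^2)
  phi <- if (d$n > 1L) q / (d$n - 1L) else NA_real_
  use_mre <- switch(effects_mode,
                    auto = d$n > 3L,
                    fixed = FALSE,
                    multiplicative_random = TRUE)
  se <- if (use_mre) se_fixed * sqrt(max(1, phi)) else se_fixed
  mr_result("IVW", d$n, beta, se, cochran_q = q, dispersion_phi = phi,
            effects = if (use_mre) "multiplicative_random" else "fixed")
}

# Interpolated weighted median of the ratio estimates: order theta
# ascending, place each at the midpoint of its normalised weight band,
# p_j = (S_j - w_j/2)/S_J, and interpolate theta linearly at p = 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The inverse-variance-weighted median of the per-variant Wald ratios,
#' consistent when more than half of the total weight comes from valid
#' instruments. The point estimate interpolates the weighted empirical
#' quantile function at 0.5; the standard error is the standard deviation
#' of the estimate over `bootstrap_reps` parametric resamples, redrawing
#' each variant's exposure and outcome effects from normal distributions
#' centred on the estimates with their reported SEs.
#'
#' @param hs Harmonised variants (at least 3 usable).
#' @param bootstrap_reps Number of parametric bootstrap resamples
#'   (default 1000).
#' @param seed RNG seed for the bootstrap (required).
#' @return An [mr_result()].
#' @export
mr_weighted_median <- function(hs, bootstrap_reps = 1000L, seed) {
  if (missing(seed) || is.null(seed)) {
    stopf("weighted median: bootstrap `seed` is required")
  }
  d <- estimator_inputs(hs, 3L, "weighted median")
  w <- d$bx^2 / d$sy^2
  beta <- weighted_median_point(d$by / d$bx, w)
  boots <- with_seed(seed, {
    vapply(seq_len(bootstrap_reps), function(r) {
      bx_star <- rnorm(d$n, d$bx, d$sx)
      by_star <- rnorm(d$n, d$by, d$sy)
      weighted_median_point(by_star / bx_star, bx_star^2 / d$sy^2)
    }, numeric(1))
  })
  mr_result("weighted_median", d$n, beta, sd(boots))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with
#' a free intercept, weights 1/se_outcome^2, after orienting every variant
#' so its exposure effect is non-negative (both betas negated where
#' needed). The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy and
#' is an audit on IVW validity. Standard errors are inflated by
#' sqrt(max(1, RSS_w/(J-2))) (multiplicative residual dispersion, floored
#' at 1); p-values use the normal approximation.
#'
#' @param hs Harmonised variants (at least 3 usable).
#' @return An [mr_result()] with intercept fields populated.
#' @export
mr_egger <- function(hs) {
  d <- estimator_inputs(hs, 3L, "MR-Egger")
  flip <- d$bx < 0
  bx <- ifelse(flip, -d$bx, d$bx)
  by <- ifelse(flip, -d$by, d$by)
  if (length(unique(bx)) == 1L) {
    stopf("MR-Egger: exposure effects are collinear after orientation")
  }
  w <- 1 / d$sy^2
  x_mat <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x_mat, w * x_mat)
  coef <- solve(xtwx, crossprod(x_mat, w * by))
  fitted <- drop(x_mat %*% coef)
  rss_w <- sum(w * (by - fitted)^2)
  scale <- max(1, rss_w / (d$n - 2L))
  vcov <- solve(xtwx) * scale
  se <- sqrt(diag(vcov))
  slope <- unname(coef["slope", 1])
  slope_se <- unname(se["slope"])
  int <- unname(coef["intercept", 1])
  int_se <- unname(se["intercept"])
  mr_result("MR_Egger", d$n, slope, slope_se,
            cochran_q = rss_w, dispersion_phi = rss_w / (d$n - 2L),
            intercept = int, intercept_se = int_se,
            intercept_p = 2 * pnorm(-abs(int / int_se)))
}

# Profile log-likelihood of the causal effect, accounting for measurement
# error in both exposure and outcome effects.
raps_loglik <- function(beta, bx, sx, by, sy) {
  -0.5 * sum((by - beta * bx)^2 / (sy^2 + beta^2 * sx^2))
}

#' Robust adjusted profile score, simple model
#'
#' Maximises the profile log-likelihood
#' l(beta) = -1/2 sum_j (by_j - beta bx_j)^2 / (se_y_j^2 + beta^2 se_x_j^2),
#' which accounts for measurement error in the exposure effects (no
#' overdispersion parameter, squared-error loss). The optimum is found
#' numerically on a bracket around the IVW estimate, widening if needed;
#' the standard error comes from the numerical observed information
#' (central second difference) at the optimum.
#'
#' @param hs Harmonised variants (at least 2 usable).
#' @return An [mr_result()].
#' @export
mr_raps <- function(hs) {
  d <- estimator_inputs(hs, 2L, "MR-RAPS")
  ivw <- mr_ivw(hs, effects_mode = "fixed")
  half <- max(1, 10 * abs(ivw$beta), 20 * ivw$se)
  obj <- function(b) raps_loglik(b, d$bx, d$sx, d$by, d$sy)
  beta_hat <- NULL
  for (attempt in 1:6) {
    lo <- ivw$beta - half
    hi <- ivw$beta + half
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-12)
    edge <- min(opt$maximum - lo, hi - opt$maximum) < 1e-6 * (hi - lo)
    if (!edge) {
      beta_hat <- opt$maximum
      break
    }
    half <- half * 10
  }
  if (is.null(beta_hat)) {
    stopf("MR-RAPS failed to find an interior maximum in [%g, %g]", lo, hi)
  }
  h <- 1e-4 * (1 + abs(beta_hat))
  info <- -(obj(beta_hat + h) - 2 * obj(beta_hat) + obj(beta_hat - h)) / h^2
  if (!is.finite(info) || info <= 0) {
    stopf("MR-RAPS: observed information non-positive at the optimum")
  }
  mr_result("MR_RAPS", d$n, beta_hat, 1 / sqrt(info))
}

#' Convert an estimator result to a report row on the odds-ratio scale
#'
#' For binary outcomes (log-odds betas) the estimate and CI bounds are
#' exponentiated into an odds ratio per SD of exposure; continuous
#' outcomes pass through with the OR fields absent (`NA`). Egger intercept
#' columns are populated only for MR-Egger results.
#'
#' @param result An [mr_result()].
#' @param outcome_id Outcome label for the row.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param selection Selection-tier label (default `"primary"`).
#' @return A one-row data frame in the report schema (see
#'   [write_report()]).
#' @export
to_odds_scale <- function(result, outcome_id = "outcome",
                          trait_type = c("binary", "continuous"),
                          selection = "primary") {
  stopifnot(inherits(result, "mr_result"))
  trait_type <- match.arg(trait_type)
  binary <- trait_type == "binary"
  as_report_rows(data.frame(
    outcome_id = outcome_id, selection = selection, method = result$method,
    n_snp = result$n_snp, beta = result$beta, se = result$se,
    or_ = if (binary) exp(result$beta) else NA_real_,
    ci_low = if (binary) exp(result$ci_low) else NA_real_,
    ci_high = if (binary) exp(result$ci_high) else NA_real_,
    pval = result$pval,
    egger_intercept = result$intercept, intercept_se = result$intercept_se,
    intercept_p = result$intercept_p, stringsAsFactors = FALSE
  ))
}
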