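#' Power query for two-sample MR with a binary outcome
#'
#' Bundles the quantities the closed-form power approximation needs. The
#' approximation treats an MR study as an ordinary association study whose
#' effective sample size is the outcome sample size multiplied by the
#' variance in the exposure explained by the instruments (r-squared): the
#' non-centrality of the causal log-odds ratio b is
#' sqrt(N r2 K (1-K)) * |b|, with K the case fraction.
#'
#' @param n_cases,n_controls Outcome case and non-case counts.
#' @param r2_instruments Variance in the exposure explained by the
#'   instruments, in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @param target_power Target power for [detectable_or()] (default 0.80).
#' @param odds_ratio Optional OR (per SD of exposure) for
#'   [power_at_or()]; may be a vector.
#' @return An object of class `power_query`.
#' @export
power_query <- function(n_cases, n_controls, r2_instruments,
                        alpha = 0.05, target_power = 0.80,
                        odds_ratio = NULL) {
  if (n_cases <= 0 || n_controls <= 0) {
    stopf("`n_cases` and `n_controls` must be positive")
  }
  check_fraction(r2_instruments, "r2_instruments",
                 closed_low = FALSE, closed_high = FALSE)
  check_fraction(alpha, "alpha", closed_low = FALSE, closed_high = FALSE)
  check_fraction(target_power, "target_power",
                 closed_low = FALSE, closed_high = FALSE)
  structure(
    list(n_cases = unname(n_cases), n_controls = unname(n_controls),
         r2_instruments = unname(r2_instruments), alpha = unname(alpha),
         target_power = unname(target_power),
         odds_ratio = if (!is.null(odds_ratio)) unname(odds_ratio)),
    class = "power_query"
  )
}

power_scale <- function(q) {
  n <- q$n_cases + q$n_controls
  k <- q$n_cases / n
  if (k <= 0 || k >= 1) stopf("degenerate case fraction K = %g", k)
  sqrt(n * q$r2_instruments * k * (1 - k))
}

#' Smallest detectable odds ratio at target power
#'
#' Inverts the power approximation: the detectable causal log-OR per SD of
#' exposure satisfies |log OR| = (z_{1-alpha/2} + z_{power}) /
#' sqrt(N r2 K (1-K)). Both directions are returned, protective
#' (exp(-|log OR|) < 1) and harmful (exp(+|log OR|) > 1).
#'
#' @param q A [power_query()].
#' @return Named numeric vector `c(or_protective, or_harmful)`.
#' @export
detectable_or <- function(q) {
  stopifnot(inherits(q, "power_query"))
  log_or <- (qnorm(1 - q$alpha / 2) + qnorm(q$target_power)) / power_scale(q)
  c(or_protective = exp(-log_or), or_harmful = exp(log_or))
}

#' Power to detect a given odds ratio
#'
#' power = Phi( sqrt(N r2 K (1-K)) |log OR| - z_{1-alpha/2} ). At OR = 1
#' this returns exactly Phi(-z_{1-alpha/2}), i.e. half the two-sided
#' alpha — the probability of rejecting in one prespecified direction
#' under the null.
#'
#' @param q A [power_query()] with `odds_ratio` set (vectorised).
#' @return Numeric vector of power values in (0, 1).
#' @export
power_at_or <- function(q) {
  stopifnot(inherits(q, "power_query"))
  if (is.null(q$odds_ratio)) stopf("`odds_ratio` must be set on the query")
  pnorm(power_scale(q) * abs(log(q$odds_ratio)) - qnorm(1 - q$alpha / 2))
}
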