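`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer `seed` is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# 97.5% and 80% standard-normal quantiles at full precision; used for all
# confidence intervals and the power approximation.
z_ci <- function(alpha = 0.05) qnorm(1 - alpha / 2)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Two-sided normal p-value from a z-score, floored to stay inside (0, 1]
# when the tail underflows.
two_sided_p <- function(z) pmax(2 * pnorm(-abs(z)), 1e-300)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_fraction <- function(x, name, closed_low = TRUE, closed_high = TRUE) {
  lo_ok <- if (closed_low) x >= 0 else x > 0
  hi_ok <- if (closed_high) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stopf("`%s` must be a proportion in %s0, 1%s, got %s",
          name, if (closed_low) "[" else "(",
          if (closed_high) "]" else ")", format(x))
  }
  invisible(x)
}
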