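#' Instrument-selection parameters
#'
#' Thresholds for selecting genetic instruments from an exposure panel:
#' a genome-wide significance threshold on the variant-exposure p-value
#' (default 5e-8; a liberal tier conventionally uses 5e-6), an LD pruning
#' threshold for independence (pairwise r-squared below `clump_r2`), a
#' weak-instrument screen on the per-variant F-statistic, and the minimum
#' r-squared for accepting a correlated proxy when an instrument is absent
#' from an outcome panel.
#'
#' @param p_threshold Strict upper bound on instrument p-values (default
#'   5e-8).
#' @param clump_r2 Variants with r-squared at or above this against a
#'   retained instrument are pruned (default 0.001).
#' @param f_min Minimum per-variant F-statistic (default 10).
#' @param proxy_r2_min Proxies must exceed this r-squared (default 0.8).
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             f_min = 10, proxy_r2_min = 0.8) {
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stopf("`p_threshold` must lie in (0, 1)")
  }
  check_fraction(clump_r2, "clump_r2")
  if (f_min < 0) stopf("`f_min` must be >= 0")
  if (!(proxy_r2_min > 0 && proxy_r2_min <= 1)) {
    stopf("`proxy_r2_min` must lie in (0, 1]")
  }
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 f_min = f_min, proxy_r2_min = proxy_r2_min),
            class = "selection_params")
}

#' Per-variant instrument-strength F-statistic
#'
#' The standard summary-statistic approximation F = (beta/se)^2, i.e. the
#' squared z-score of the variant-exposure association. F > 10 is the
#' conventional weak-instrument screen.
#'
#' @param beta,se Effect estimate(s) and standard error(s); or pass a data
#'   frame / one-row record with `beta` and `se` columns as `beta`.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta) || is.list(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  if (any(se <= 0)) stopf("`se` must be > 0")
  (beta / se)^2
}

#' Variance in the exposure explained by a variant
#'
#' For a standardised exposure, the proportion of variance explained by a
#' variant with per-allele effect beta (SD units) and effect-allele
#' frequency p is beta^2 * 2 p (1 - p); an instrument set's total is the
#' sum over its variants.
#'
#' @param beta,eaf Effect(s) in SD units and effect-allele frequency(ies);
#'   or pass a record with `beta` and `eaf` columns as `beta`.
#' @return Numeric vector of variance proportions.
#' @export
variance_explained <- function(beta, eaf = NULL) {
  if (is.data.frame(beta) || is.list(beta)) {
    eaf <- beta$eaf
    beta <- beta$beta
  }
  if (any(is.na(eaf))) {
    stopf("effect-allele frequency is missing; variance explained needs eaf")
  }
  beta^2 * 2 * eaf * (1 - eaf)
}

#' Greedy LD clumping of an exposure panel into an instrument set
#'
#' Repeatedly retains the remaining variant with the smallest p-value that
#' passes `p < p_threshold` (strict) and `F >= f_min`, then discards every
#' remaining variant with r-squared at or above `clump_r2` against it.
#' Ties in p-value are broken by (chromosome, position), then variant_id,
#' so the result is deterministic and independent of input row order.
#'
#' @param panel Exposure [trait_panel()].
#' @param ld An [ld_table()]; `NULL` means all variants independent.
#' @param params A [selection_params()].
#' @return An object of class `instrument_set`: list with `variants` (the
#'   retained records, in selection order), `per_variant_f`, `mean_f`, and
#'   `r2_total` (summed variance explained; `NA` if any retained EAF is
#'   missing).
#' @export
clump <- function(panel, ld = NULL, params = selection_params()) {
  stopifnot(inherits(panel, "trait_panel"))
  ld <- ld %||% ld_table()
  rec <- panel$records
  rec$.f <- f_statistic(rec$beta, rec$se)
  cand <- rec[rec$pval < params$p_threshold & rec$.f >= params$f_min, ,
              drop = FALSE]
  if (nrow(cand) == 0L) {
    stopf("no instruments pass p < %g and F >= %g in panel '%s'",
          params$p_threshold, params$f_min, panel$trait_id)
  }
  ord <- order(cand$pval, cand$chromosome, cand$position, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  keep <- character(0)
  remaining <- cand$variant_id
  while (length(remaining) > 0L) {
    head_id <- remaining[1L]
    keep <- c(keep, head_id)
    r2 <- ld_r2(ld, head_id, remaining)
    remaining <- remaining[r2 < params$clump_r2 & remaining != head_id]
  }
  variants <- cand[match(keep, cand$variant_id), , drop = FALSE]
  per_f <- setNames(variants$.f, variants$variant_id)
  variants$.f <- NULL
  rownames(variants) <- NULL
  r2_total <- if (any(is.na(variants$eaf))) NA_real_ else {
    sum(variance_explained(variants$beta, variants$eaf))
  }
  structure(
    list(variants = variants, per_variant_f = per_f,
         mean_f = mean(per_f), r2_total = r2_total, params = params),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d variants; mean F = %.1f; r2 total = %s\n",
              nrow(x$variants), x$mean_f,
              ifelse(is.na(x$r2_total), "NA", format(x$r2_total, digits = 3))))
  invisible(x)
}

#' Find an outcome association for an instrument, via proxy if needed
#'
#' If the variant is present in the outcome panel its record is returned
#' unchanged. Otherwise the proxy table is searched for the highest-r2
#' proxy with r2 strictly above `params$proxy_r2_min` that is present in
#' the outcome panel; ties are broken by proxy id. If none qualifies the
#' function returns `NULL` — absence is a valid result, and the variant is
#' simply dropped from that outcome's analysis.
#'
#' @param variant_id Instrument variant id.
#' @param outcome Outcome [trait_panel()].
#' @param proxies Data frame `variant_id`, `proxy_id`, `r2`, or `NULL`.
#' @param params A [selection_params()].
#' @return A one-row record (with attribute `proxy = list(id, r2)` when a
#'   proxy was substituted), or `NULL`.
#' @export
find_proxy <- function(variant_id, outcome, proxies = NULL,
                       params = selection_params()) {
  stopifnot(inherits(outcome, "trait_panel"))
  direct <- panel_record(outcome, variant_id)
  if (!is.null(direct)) return(direct)
  if (is.null(proxies)) return(NULL)
  cand <- proxies[proxies$variant_id == variant_id &
                    proxies$r2 > params$proxy_r2_min &
                    proxies$proxy_id %in% outcome$records$variant_id, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$r2, cand$proxy_id), , drop = FALSE]
  rec <- panel_record(outcome, cand$proxy_id[1L])
  attr(rec, "proxy") <- list(id = cand$proxy_id[1L], r2 = cand$r2[1L])
  rec
}
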