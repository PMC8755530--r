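HARMONISE_ACTIONS <- c("kept", "flipped", "strand_flipped",
                       "dropped_palindromic", "dropped_allele_mismatch",
                       "dropped_missing")

is_palindromic <- function(effect, other) {
  unname(STRAND_COMPLEMENT[effect]) == other
}

harmonised_row <- function(variant_id, effect_allele = NA, other_allele = NA,
                           beta_exposure = NA_real_, se_exposure = NA_real_,
                           beta_outcome = NA_real_, se_outcome = NA_real_,
                           eaf_exposure = NA_real_, action,
                           outcome_variant = NA_character_,
                           proxy_r2 = NA_real_) {
  data.frame(variant_id = variant_id, effect_allele = effect_allele,
             other_allele = other_allele, beta_exposure = beta_exposure,
             se_exposure = se_exposure, beta_outcome = beta_outcome,
             se_outcome = se_outcome, eaf_exposure = eaf_exposure,
             action = action, outcome_variant = outcome_variant,
             proxy_r2 = proxy_r2, stringsAsFactors = FALSE)
}

#' Harmonise one exposure/outcome record pair onto a common effect allele
#'
#' Aligns the outcome association to the exposure's effect allele. Rules,
#' in order: identical alleles are kept as-is; swapped alleles flip the
#' outcome (beta negated, EAF complemented); alleles that match only after
#' strand complementation (A<->T, C<->G) are complemented first and logged
#' as `strand_flipped`; anything else is dropped as an allele mismatch.
#'
#' Palindromic pairs (A/T or C/G) are strand-ambiguous: allele labels
#' cannot distinguish a swap from a strand flip, so orientation is decided
#' by allele-frequency agreement instead — but only when the exposure EAF
#' is given (otherwise `dropped_palindromic`), the outcome EAF is given,
#' and both minor-allele frequencies are below `maf_threshold` (near-0.5
#' frequencies are uninformative and the variant is dropped). After
#' nominal label alignment, a frequency disagreement flips the outcome
#' once more; the logged action reflects the net effect on the outcome
#' beta (`kept` or `flipped`).
#'
#' @param exposure,outcome One-row association records sharing
#'   `variant_id`.
#' @param maf_threshold Palindromic ambiguity window (default 0.42): both
#'   minor-allele frequencies must fall below it for frequency alignment.
#' @return A one-row data frame (a harmonised variant) with an `action`
#'   column; records whose action starts with `dropped` must not reach any
#'   estimator.
#' @export
harmonise_pair <- function(exposure, outcome, maf_threshold = 0.42) {
  e <- as.list(exposure)
  o <- as.list(outcome)
  if (!identical(e$variant_id, o$variant_id)) {
    stopf("variant_id mismatch: '%s' vs '%s'", e$variant_id, o$variant_id)
  }
  base <- function(action, beta_out = NA_real_, se_out = NA_real_) {
    harmonised_row(e$variant_id, e$effect_allele, e$other_allele,
                   e$beta, e$se, beta_out, se_out, e$eaf, action,
                   outcome_variant = o$variant_id)
  }

  oe <- o$effect_allele
  oo <- o$other_allele
  ob <- o$beta
  of <- o$eaf

  if (is_palindromic(e$effect_allele, e$other_allele)) {
    # Outcome allele set must be the same palindromic pair (its strand
    # complement is itself, up to swap).
    if (!setequal(c(oe, oo), c(e$effect_allele, e$other_allele))) {
      return(base("dropped_allele_mismatch"))
    }
    if (is.na(e$eaf) || is.na(of)) return(base("dropped_palindromic"))
    # Nominal label alignment first (swap detected from labels), then
    # orientation from frequencies.
    if (oe != e$effect_allele) {
      ob <- -ob
      of <- 1 - of
    }
    if (min(e$eaf, 1 - e$eaf) >= maf_threshold ||
        min(of, 1 - of) >= maf_threshold) {
      return(base("dropped_palindromic"))
    }
    if ((e$eaf < 0.5) != (of < 0.5)) {
      ob <- -ob
      of <- 1 - of
    }
    action <- if (identical(ob, o$beta)) "kept" else "flipped"
    return(base(action, ob, o$se))
  }

  strand <- FALSE
  if (!setequal(c(oe, oo), c(e$effect_allele, e$other_allele))) {
    oe2 <- unname(STRAND_COMPLEMENT[oe])
    oo2 <- unname(STRAND_COMPLEMENT[oo])
    if (setequal(c(oe2, oo2), c(e$effect_allele, e$other_allele))) {
      oe <- oe2
      oo <- oo2
      strand <- TRUE
    } else {
      return(base("dropped_allele_mismatch"))
    }
  }
  if (oe == e$effect_allele && oo == e$other_allele) {
    return(base(if (strand) "strand_flipped" else "kept", ob, o$se))
  }
  # Alleles swapped relative to the exposure: negate and complement.
  ob <- -ob
  return(base(if (strand) "strand_flipped" else "flipped", ob, o$se))
}

#' Harmonise an instrument set against an outcome panel
#'
#' For each instrument: the outcome record is located with [find_proxy()]
#' (the variant itself, or its best proxy above `params$proxy_r2_min`);
#' instruments absent from the outcome with no qualifying proxy are logged
#' as `dropped_missing`. Direct hits are aligned with [harmonise_pair()].
#' Proxy records are taken as already oriented to the index variant, so
#' their beta/SE/EAF are adopted directly as the outcome association of
#' the instrument (proxy id and r-squared logged).
#'
#' @param instruments An [instrument_set()] from [clump()].
#' @param outcome Outcome [trait_panel()].
#' @param proxies Optional proxy table (`variant_id`, `proxy_id`, `r2`).
#' @param params A [selection_params()].
#' @param maf_threshold Passed to [harmonise_pair()].
#' @return A data frame of harmonised variants (class `harmonised`), one
#'   row per instrument, with an `action` audit column. Errors if no
#'   record is kept.
#' @export
harmonise_panels <- function(instruments, outcome, proxies = NULL,
                             params = selection_params(),
                             maf_threshold = 0.42) {
  stopifnot(inherits(instruments, "instrument_set"),
            inherits(outcome, "trait_panel"))
  exp_rec <- instruments$variants
  if (nrow(exp_rec) == 0L) stopf("instrument set is empty")
  rows <- vector("list", nrow(exp_rec))
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, , drop = FALSE]
    o <- find_proxy(e$variant_id, outcome, proxies, params)
    if (is.null(o)) {
      rows[[i]] <- harmonised_row(e$variant_id, e$effect_allele,
                                  e$other_allele, e$beta, e$se,
                                  eaf_exposure = e$eaf,
                                  action = "dropped_missing")
    } else if (!is.null(attr(o, "proxy"))) {
      px <- attr(o, "proxy")
      rows[[i]] <- harmonised_row(e$variant_id, e$effect_allele,
                                  e$other_allele, e$beta, e$se,
                                  beta_outcome = o$beta, se_outcome = o$se,
                                  eaf_exposure = e$eaf, action = "kept",
                                  outcome_variant = px$id, proxy_r2 = px$r2)
    } else {
      rows[[i]] <- harmonise_pair(e, o, maf_threshold = maf_threshold)
    }
  }
  h <- do.call(rbind, rows)
  class(h) <- c("harmonised", class(h))
  if (sum(!startsWith(h$action, "dropped")) == 0L) {
    stopf("harmonisation kept zero records for outcome '%s'",
          outcome$trait_id)
  }
  h
}

# Usable (non-dropped) harmonised records, for the estimators.
kept_records <- function(hs) {
  hs <- as.data.frame(hs)
  hs[!startsWith(hs$action, "dropped"), , drop = FALSE]
}

#' Assemble harmonised variants directly from aligned panels
#'
#' Joins an exposure and an outcome panel on `variant_id`, assuming both
#' already report effects on the same effect allele (as the synthetic
#' generator guarantees). Useful for simulation studies that bypass
#' selection and corruption.
#'
#' @param exposure,outcome [trait_panel()]s.
#' @return A `harmonised` data frame with all actions `kept`.
#' @export
as_harmonised <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "trait_panel"), inherits(outcome, "trait_panel"))
  common <- intersect(exposure$records$variant_id, outcome$records$variant_id)
  e <- exposure$records[match(common, exposure$records$variant_id), ]
  o <- outcome$records[match(common, outcome$records$variant_id), ]
  h <- harmonised_row(common, e$effect_allele, e$other_allele,
                      e$beta, e$se, o$beta, o$se, e$eaf, "kept",
                      outcome_variant = common)
  class(h) <- c("harmonised", class(h))
  h
}

#' Write a harmonisation audit log as TSV
#' @param hs A `harmonised` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonisation_log <- function(hs, path) {
  write.table(as.data.frame(hs), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}
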