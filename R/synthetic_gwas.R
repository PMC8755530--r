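#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defines the full generative model for a pair of GWAS summary-statistic
#' panels (exposure and outcome) with the statistical structure two-sample
#' MR assumes. Per variant j: a true exposure effect gamma_j ~
#' N(0, `gamma_sd`), an effect-allele frequency ~ U(0.05, 0.95), a direct
#' (pleiotropic) outcome effect alpha_j ~ N(`pleiotropy_mean`,
#' `pleiotropy_sd`) whose correlation with |gamma_j| is `inside_violation`
#' (a Gaussian copula; 0 means the InSIDE assumption holds), and a total
#' outcome effect `true_beta` * gamma_j + sign(gamma_j) * alpha_j on the
#' log-odds scale for binary outcomes. Direct effects are defined on each
#' variant's exposure-increasing orientation — the scale on which a
#' nonzero `pleiotropy_mean` means directional pleiotropy and on which the
#' MR-Egger intercept estimates it — and sign(gamma_j) carries them back
#' to the reported effect allele. Estimated effects add normal noise at GWAS precision:
#' exposure SE = 1/sqrt(2 eaf (1-eaf) n_exposure); binary-outcome SE =
#' 1/sqrt(2 eaf (1-eaf) n_outcome K (1-K)) with K = `case_fraction`.
#'
#' The corruption fractions control [corrupt_for_harmonisation()]; LD is
#' controlled by `ld_block_size` (see [generate_ld_and_proxies()]). A fixed
#' seed makes every product byte-identical: one RNG stream per seed,
#' consumed in documented order (gamma, EAF, exposure noise, pleiotropy,
#' outcome noise; corruption and LD each reseed deterministically from
#' `seed`).
#'
#' @param j_variants Number of variants (>= 1).
#' @param n_exposure,n_outcome GWAS sample sizes for the two samples.
#' @param true_beta Causal effect of the exposure on the outcome (log-OR
#'   per SD of exposure for binary outcomes).
#' @param gamma_sd SD of true per-variant exposure effects (> 0), SD units.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct effects;
#'   `pleiotropy_mean != 0` gives directional pleiotropy.
#' @param inside_violation Copula correlation in \[-1, 1\] between |gamma_j|
#'   and alpha_j; nonzero violates InSIDE.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case proportion K in (0, 1) for binary outcomes.
#' @param palindromic_fraction,allele_swap_fraction,strand_flip_fraction,missing_eaf_fraction
#'   Proportions of variants hit by each corruption in
#'   [corrupt_for_harmonisation()].
#' @param ld_block_size Size of LD blocks in [generate_ld_and_proxies()]
#'   (1 = all variants independent).
#' @param seed Integer RNG seed (required).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(j_variants = 100L,
                       n_exposure = 3636L,
                       n_outcome = 1e6,
                       true_beta = -0.04,
                       gamma_sd = 0.15,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       inside_violation = 0,
                       outcome_type = c("binary", "continuous"),
                       case_fraction = 0.04,
                       palindromic_fraction = 0,
                       allele_swap_fraction = 0,
                       strand_flip_fraction = 0,
                       missing_eaf_fraction = 0,
                       ld_block_size = 1L,
                       seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stopf("`seed` is required for reproducibility")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be a single integer")
  }
  if (!is.numeric(j_variants) || j_variants < 1) {
    stopf("`j_variants` must be >= 1")
  }
  if (!is.numeric(gamma_sd) || gamma_sd <= 0) stopf("`gamma_sd` must be > 0")
  if (pleiotropy_sd < 0) stopf("`pleiotropy_sd` must be >= 0")
  if (abs(inside_violation) > 1) stopf("`inside_violation` must lie in [-1, 1]")
  check_fraction(case_fraction, "case_fraction",
                 closed_low = FALSE, closed_high = FALSE)
  for (f in c("palindromic_fraction", "allele_swap_fraction",
              "strand_flip_fraction", "missing_eaf_fraction")) {
    check_fraction(get(f), f)
  }
  if (ld_block_size < 1) stopf("`ld_block_size` must be >= 1")
  structure(
    list(j_variants = as.integer(j_variants),
         n_exposure = n_exposure, n_outcome = n_outcome,
         true_beta = true_beta, gamma_sd = gamma_sd,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         inside_violation = inside_violation,
         outcome_type = outcome_type, case_fraction = case_fraction,
         palindromic_fraction = palindromic_fraction,
         allele_swap_fraction = allele_swap_fraction,
         strand_flip_fraction = strand_flip_fraction,
         missing_eaf_fraction = missing_eaf_fraction,
         ld_block_size = as.integer(ld_block_size),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic non-random variant annotations: ids, coordinates, alleles.
sim_variant_frame <- function(j) {
  data.frame(
    variant_id = sprintf("rs%07d", seq_len(j)),
    chromosome = as.character(rep_len(1:22, j)),
    position = 1000000L + 10000L * seq_len(j),
    effect_allele = "A",
    other_allele = "G",
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-sample GWAS
#'
#' Draws exposure and outcome summary-statistic panels from the generative
#' model described in [sim_config()], together with the per-variant truth
#' (gamma_j, alpha_j) for parameter-recovery checks. Two-sided normal
#' p-values are attached to both panels; the outcome panel carries
#' case/control counts when `outcome_type = "binary"`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (both
#'   [trait_panel()]s) and `truth` (data frame `variant_id`, `gamma`,
#'   `alpha`, `total_outcome_effect`).
#' @export
generate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  j <- config$j_variants
  vf <- sim_variant_frame(j)
  with_seed(config$seed, {
    gamma <- rnorm(j, 0, config$gamma_sd)
    eaf <- runif(j, 0.05, 0.95)
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
    beta_x <- gamma + rnorm(j, 0, se_x)
    # Gaussian copula between |gamma_j| and alpha_j: the half-normal CDF of
    # |gamma| is mapped to a standard-normal score, then mixed with fresh
    # noise at correlation `inside_violation`.
    z_alpha <- rnorm(j)
    u <- pmin(pmax(2 * pnorm(abs(gamma) / config$gamma_sd) - 1, 1e-12), 1 - 1e-12)
    z_gamma <- qnorm(u)
    rho <- config$inside_violation
    alpha <- config$pleiotropy_mean +
      config$pleiotropy_sd * (rho * z_gamma + sqrt(1 - rho^2) * z_alpha)
    # Direct effects are defined on the exposure-increasing orientation of
    # each variant (the scale on which a directional-pleiotropy mean and
    # the Egger intercept are interpretable); sign(gamma) maps them back
    # to the reported effect allele.
    total <- config$true_beta * gamma + sign(gamma) * alpha
    k_term <- if (config$outcome_type == "binary") {
      config$case_fraction * (1 - config$case_fraction)
    } else 1
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome * k_term)
    beta_y <- total + rnorm(j, 0, se_y)
  })

  exp_rec <- cbind(vf, data.frame(
    eaf = eaf, beta = beta_x, se = se_x,
    pval = two_sided_p(beta_x / se_x), n = config$n_exposure
  ))
  out_rec <- cbind(vf, data.frame(
    eaf = eaf, beta = beta_y, se = se_y,
    pval = two_sided_p(beta_y / se_y), n = config$n_outcome
  ))
  if (config$outcome_type == "binary") {
    out_rec$n_cases <- round(config$case_fraction * config$n_outcome)
    out_rec$n_controls <- config$n_outcome - out_rec$n_cases
    out_rec$n <- out_rec$n_cases + out_rec$n_controls
  }
  list(
    exposure = trait_panel(exp_rec, "sim_exposure", "continuous"),
    outcome = trait_panel(out_rec, "sim_outcome", config$outcome_type),
    truth = data.frame(variant_id = vf$variant_id, gamma = gamma,
                       alpha = alpha, total_outcome_effect = total,
                       stringsAsFactors = FALSE)
  )
}

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Corrupt a panel pair to exercise harmonisation
#'
#' Applies the record-level corruptions real summary statistics exhibit, in
#' documented order and each to an independently drawn subset of variants:
#' (1) conversion to a palindromic allele pair (A/T), applied consistently
#' to outcome and, when supplied, exposure, so orientation is recoverable
#' only through allele frequencies; (2) strand complementation of the
#' outcome alleles (information-preserving); (3) allele swap in the outcome
#' with beta negated and EAF complemented (information-preserving); (4)
#' masking of exposure EAFs (requires `exposure`). The returned manifest
#' records which corruption hit which variant, so round-trip tests can
#' verify that harmonisation restores the original signed effects for every
#' variant it does not deliberately drop.
#'
#' @param outcome A [trait_panel()] to corrupt.
#' @param config A [sim_config()]; the corruption fractions and seed apply.
#' @param exposure Optional exposure [trait_panel()]; needed for
#'   palindromic conversion to be reconcilable and for EAF masking.
#' @return List with `outcome` (corrupted panel), `exposure` (corrupted
#'   panel or `NULL`), and `manifest` (data frame of logical flags per
#'   variant).
#' @export
corrupt_for_harmonisation <- function(outcome, config, exposure = NULL) {
  stopifnot(inherits(outcome, "trait_panel"), inherits(config, "sim_config"))
  out <- outcome$records
  exp_rec <- if (!is.null(exposure)) exposure$records else NULL
  if (config$missing_eaf_fraction > 0 && is.null(exp_rec)) {
    stopf("missing_eaf_fraction > 0 masks exposure EAFs; supply `exposure`")
  }
  j <- nrow(out)
  with_seed(config$seed + 1L, {
    pal <- runif(j) < config$palindromic_fraction
    strand <- runif(j) < config$strand_flip_fraction
    swap <- runif(j) < config$allele_swap_fraction
    mask <- runif(j) < config$missing_eaf_fraction
  })

  if (any(pal)) {
    out$effect_allele[pal] <- "A"
    out$other_allele[pal] <- "T"
    if (!is.null(exp_rec)) {
      i <- match(out$variant_id[pal], exp_rec$variant_id)
      ok <- !is.na(i)
      exp_rec$effect_allele[i[ok]] <- "A"
      exp_rec$other_allele[i[ok]] <- "T"
    }
  }
  if (any(strand)) {
    out$effect_allele[strand] <- unname(STRAND_COMPLEMENT[out$effect_allele[strand]])
    out$other_allele[strand] <- unname(STRAND_COMPLEMENT[out$other_allele[strand]])
  }
  if (any(swap)) {
    tmp <- out$effect_allele[swap]
    out$effect_allele[swap] <- out$other_allele[swap]
    out$other_allele[swap] <- tmp
    out$beta[swap] <- -out$beta[swap]
    out$eaf[swap] <- 1 - out$eaf[swap]
  }
  if (any(mask) && !is.null(exp_rec)) {
    i <- match(out$variant_id[mask], exp_rec$variant_id)
    exp_rec$eaf[i[!is.na(i)]] <- NA_real_
  }

  corrupted_outcome <- outcome
  corrupted_outcome$records <- out
  corrupted_exposure <- NULL
  if (!is.null(exposure)) {
    corrupted_exposure <- exposure
    corrupted_exposure$records <- exp_rec
  }
  list(
    outcome = corrupted_outcome,
    exposure = corrupted_exposure,
    manifest = data.frame(variant_id = out$variant_id, palindromic = pal,
                          strand_flipped = strand, allele_swapped = swap,
                          eaf_masked = mask, stringsAsFactors = FALSE)
  )
}

#' Generate a block-structured LD table and proxy table
#'
#' Partitions the panel's variants (in order) into blocks of
#' `config$ld_block_size`; pairwise r-squared within a block is drawn
#' uniformly from (0.5, 1) and is exactly 0 between blocks. The proxy table
#' lists, for each variant, the other members of its block with their
#' r-squared — a local stand-in for an online LD/proxy lookup service.
#'
#' @param panel A [trait_panel()].
#' @param config A [sim_config()]; `ld_block_size` and `seed` apply.
#' @return List with `ld` (an `ld_table`) and `proxies` (data frame
#'   `variant_id`, `proxy_id`, `r2`).
#' @export
generate_ld_and_proxies <- function(panel, config) {
  stopifnot(inherits(panel, "trait_panel"), inherits(config, "sim_config"))
  ids <- panel$records$variant_id
  if (length(ids) == 0L) stopf("panel is empty")
  block <- ceiling(seq_along(ids) / config$ld_block_size)
  pairs <- data.frame(variant_a = character(0), variant_b = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE)
  with_seed(config$seed + 2L, {
    for (b in unique(block)) {
      members <- ids[block == b]
      if (length(members) < 2L) next
      cmb <- utils::combn(members, 2L)
      pairs <- rbind(pairs, data.frame(
        variant_a = cmb[1, ], variant_b = cmb[2, ],
        r2 = runif(ncol(cmb), 0.5, 1), stringsAsFactors = FALSE
      ))
    }
  })
  ld <- ld_table(pairs)
  proxies <- rbind(
    data.frame(variant_id = pairs$variant_a, proxy_id = pairs$variant_b,
               r2 = pairs$r2, stringsAsFactors = FALSE),
    data.frame(variant_id = pairs$variant_b, proxy_id = pairs$variant_a,
               r2 = pairs$r2, stringsAsFactors = FALSE)
  )
  list(ld = ld, proxies = proxies)
}

#' Pairwise LD table
#'
#' A symmetric lookup of pairwise r-squared between variants; any pair not
#' listed has r-squared 0, and every variant has r-squared 1 with itself.
#'
#' @param pairs Data frame with columns `variant_a`, `variant_b`, `r2`.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- data.frame(variant_a = character(0), variant_b = character(0),
                        r2 = numeric(0), stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stopf("r2 must lie in [0, 1]")
  structure(list(pairs = pairs), class = "ld_table")
}

#' Read an LD table from a TSV of (variant_a, variant_b, r2)
#' @param path Path to the TSV.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  ld_table(read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
}

#' Look up pairwise r-squared in an LD table
#'
#' @param ld An [ld_table()].
#' @param a,b Variant identifiers (vectorised, recycled).
#' @return Numeric vector of r-squared values: 1 on the diagonal, 0 for
#'   absent pairs, symmetric in `a` and `b`.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  tab <- setNames(ld$pairs$r2, key(ld$pairs$variant_a, ld$pairs$variant_b))
  out <- unname(tab[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}
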