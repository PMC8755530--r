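---
title: "Two-sample Mendelian randomisation with summr: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomisation with summr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summr)
```

## The model

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure X on an outcome Y from GWAS summary statistics alone, using
genetic variants as instrumental variables. For variant j, let
$\hat\gamma_j$ (SE $\sigma_{Xj}$) be its estimated association with the
exposure in one sample and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its
association with the outcome in another. If the variant affects Y only
through X (exclusion restriction), then $\Gamma_j = \beta\,\gamma_j$ and
each Wald ratio $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the
causal effect $\beta$. For a binary outcome whose GWAS reports log odds
ratios, $\beta$ is a log-OR per SD of exposure.

summr implements five estimators over harmonised $(\hat\gamma_j,
\hat\Gamma_j)$ pairs:

- **Wald ratio** (`wald_ratio()`): $\hat\theta_j$ with the first-order
  delta SE $\sigma_{Yj}/|\hat\gamma_j|$. This ignores exposure
  uncertainty, consistently with the IVW weights below; a second-order SE
  (adding $\hat\Gamma_j^2\sigma_{Xj}^2/\hat\gamma_j^4$) is available via
  `second_order = TRUE` but off by default.
- **IVW** (`mr_ivw()`): the inverse-variance-weighted mean of the Wald
  ratios, $w_j = \hat\gamma_j^2/\sigma_{Yj}^2$ — algebraically a weighted
  regression of $\hat\Gamma$ on $\hat\gamma$ through the origin.
  Heterogeneity is summarised by Cochran's $Q = \sum_j w_j(\hat\theta_j -
  \hat\beta)^2$. In `auto` mode, with more than 3 variants the
  fixed-effects SE is multiplied by $\sqrt{\max(1, Q/(J-1))}$
  (multiplicative random effects); with 3 or fewer, fixed effects are
  used. The dispersion is floored at 1, so the random-effects SE never
  undercuts the fixed-effects SE.
- **Weighted median** (`mr_weighted_median()`): the 0.5 quantile of the
  $\hat\theta_j$ distribution under weights $w_j$, obtained by linear
  interpolation of the weighted empirical quantile function at the band
  midpoints $p_j = (S_j - w_j/2)/S_J$. It is consistent whenever more
  than half the total weight comes from valid instruments, which IVW is
  not.
- **MR-Egger** (`mr_egger()`): weighted regression of $\hat\Gamma$ on
  $\hat\gamma$ *with* a free intercept after orienting each variant so
  $\hat\gamma_j \ge 0$. The slope is the causal estimate under the InSIDE
  assumption (instrument strength independent of direct effects); the
  intercept estimates average directional pleiotropy and audits the IVW
  estimate. Its interpretability degrades sharply with few instruments —
  it is a line fitted through 3 or 4 points in the primary analysis tier.
- **MR-RAPS, simple model** (`mr_raps()`): maximises the profile
  log-likelihood
  $\ell(\beta) = -\tfrac12\sum_j (\hat\Gamma_j - \beta\hat\gamma_j)^2 /
  (\sigma_{Yj}^2 + \beta^2\sigma_{Xj}^2)$,
  which unlike IVW accounts for measurement error in the exposure
  effects. No overdispersion parameter, no robust loss — the simple
  squared-error model only; overdispersed and robust variants are out of
  scope.

## Instrument selection

`clump()` implements greedy LD clumping: repeatedly keep the remaining
variant with the smallest exposure p-value that passes `p_threshold`
(strict `<`; default genome-wide 5e-8, liberal tier 5e-6) and the
weak-instrument screen `F >= f_min` (default 10, with
$F = (\hat\gamma/\sigma_X)^2$, the standard summary-statistic
approximation), then discard every remaining variant with pairwise
$r^2 \ge$ `clump_r2` (default 0.001) against it. Ties in p-value break by
(chromosome, position), then variant id, making the result deterministic
and row-order invariant. Variance explained uses
$2p(1-p)\hat\gamma^2$ per variant (`variance_explained()`), summed over
the set; when any retained EAF is missing the total is reported as `NA`
rather than silently partial, and an externally reported constant can be
supplied to the power block instead (`power$r2_override`).

Instruments absent from an outcome panel are looked up in a local proxy
table (`find_proxy()`): the highest-$r^2$ proxy with $r^2 >$
`proxy_r2_min` (default 0.8, strict) that is present in the outcome is
substituted; otherwise the variant is dropped from that outcome only.
Proxy records are taken as already oriented to the index variant and
their effect, SE and EAF are adopted directly — the simplest contract a
local proxy table can satisfy; the proxy id and $r^2$ are logged.
Selection is performed once on the exposure panel; the fixed instrument
set is then looked up per outcome.

## Harmonisation

`harmonise_pair()` aligns each outcome record to the exposure's effect
allele: identical alleles are kept; swapped alleles flip the outcome
(beta negated, EAF complemented); alleles matching only after strand
complementation are complemented first and logged. Palindromic pairs
(A/T, C/G) are strand-ambiguous, so allele labels cannot distinguish a
swap from a strand flip. They are resolved by frequency: dropped outright
when the exposure EAF is missing; otherwise aligned by whether exposure
and outcome agree on which allele is minor, provided both minor-allele
frequencies fall below the ambiguity window `maf_threshold` (default
0.42 — near-0.5 frequencies carry no orientation information). The
EAF-present case is a conservative standard-practice extension of the
EAF-missing drop rule, and the window is configurable. Records whose
action starts with `dropped` never reach an estimator; the per-variant
action log is written as a TSV audit trail.

## Power

For a binary outcome with N = cases + non-cases and case fraction K, the
package uses the effective-sample-size approximation: an MR analysis
behaves like an association study of size $N r^2$, where $r^2$ is the
variance in the exposure explained by the instruments. The detectable
log-OR per SD of exposure at two-sided level $\alpha$ and power $1-\beta$
is

$$|\log \mathrm{OR}| = \frac{z_{1-\alpha/2} + z_{\mathrm{power}}}{\sqrt{N r^2 K (1-K)}},$$

returned in both directions by `detectable_or()`; `power_at_or()` is its
exact inverse, $\Phi(\sqrt{N r^2 K(1-K)}\,|\log\mathrm{OR}| -
z_{1-\alpha/2})$. At OR = 1 this returns exactly $\Phi(-z_{1-\alpha/2})$,
the one-directional rejection probability under the null. Normal
quantiles are used at full precision ($z_{0.975} = 1.959964$), and the
same `qnorm(0.975)` constant is used for every confidence interval in the
package. This is one of several published parameterisations of MR power;
it is the closed form on the log-odds scale with binomial variance
inflation $K(1-K)$.

## The synthetic-data generator

`generate_two_sample()` draws, per variant: a true exposure effect
$\gamma_j \sim N(0, \texttt{gamma\_sd})$; an EAF uniform on (0.05, 0.95);
an estimated exposure effect with SE $1/\sqrt{2p(1-p)\,n_{\mathrm{exp}}}$
(the standardised-trait GWAS precision); a direct effect $\alpha_j \sim
N(\texttt{pleiotropy\_mean}, \texttt{pleiotropy\_sd})$; and an outcome
effect $\beta\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j$ observed with
SE $1/\sqrt{2p(1-p)\,n_{\mathrm{out}}K(1-K)}$ for binary outcomes (the
log-odds analogue of the same approximation, consistent with the power
formula). Two design points deserve emphasis:

- **Pleiotropy is defined on the exposure-increasing orientation.**
  Reported effect alleles are arbitrary, so a directional pleiotropy mean
  is only meaningful relative to a fixed orientation — the one MR-Egger
  itself adopts. $\mathrm{sign}(\gamma_j)$ maps the oriented direct
  effect back to the reported allele. With symmetric-signed $\gamma$ and
  pleiotropy attached to the reported allele instead, directional
  pleiotropy would cancel in aggregate and no estimator could see it.
- **InSIDE violation via a Gaussian copula.** The half-normal CDF of
  $|\gamma_j|$ is mapped to a standard-normal score and mixed into
  $\alpha_j$ at correlation `inside_violation`; one parameter spans
  independence (0, InSIDE holds) to full dependence (±1).

One RNG stream per seed, consumed in documented order (γ, EAF, exposure
noise, pleiotropy, outcome noise); corruption and LD generation reseed
deterministically from `seed + 1` and `seed + 2`, so every product is
byte-identical under a fixed configuration.

`corrupt_for_harmonisation()` recreates the defects real summary
statistics exhibit — allele swaps with negated betas and complemented
EAFs, strand complements, conversion to palindromic pairs, masked
exposure EAFs — each applied to an independent random subset, with a
manifest for round-trip verification. Palindromic conversion and EAF
masking must touch the exposure panel too (otherwise the palindromic
rules cannot be exercised coherently), so the function accepts the
exposure as an optional argument and corrupts both consistently.
`generate_ld_and_proxies()` produces block-structured LD: within blocks
of `ld_block_size`, $r^2$ is uniform on (0.5, 1); between blocks it is
exactly 0. This gives clumping and proxy lookup realistic work without
modelling reference-panel LD decay.

Free parameters the underlying studies do not pin down are documented
here rather than hidden: `gamma_sd` defaults to 0.15, which at an
exposure GWAS of 3,636 gives per-variant F-statistics broadly in the
30–40 range typical of replicated cytokine instruments; the analysis
scripts use 0.07 instead, which puts greedy selection in the regime of a
small protein GWAS — roughly half a dozen genome-wide-significant
instruments jointly explaining ~8% of exposure variance.

What the generator does *not* emulate: realistic LD decay or reference
panels, sample overlap between the exposure and outcome GWAS, allele
frequency differences between populations, case-control ascertainment
effects beyond the $K(1-K)$ variance term, indels or multi-allelic
sites, and winner's-curse correction. Passing tests therefore certify
the estimators and plumbing under the stated generative model, not
robustness to everything real consortium data can contain.

## Numerical choices

- CIs and p-values use the normal reference distribution throughout, not
  t — small-J t-inference is a defensible alternative but is not used by
  the reference analyses this package mirrors; with J as low as 3 or 4
  the difference is material and is documented rather than silently
  chosen per method.
- The weighted-median SE is a parametric bootstrap (default 1000
  resamples, seed mandatory): effect pairs are redrawn from
  $N(\hat\gamma_j, \sigma_{Xj})$ and $N(\hat\Gamma_j, \sigma_{Yj})$ and
  the estimator recomputed; the SE is the SD across resamples.
- MR-RAPS maximises $\ell(\beta)$ with `optimize()` on a bracket centred
  on the IVW estimate (half-width `max(1, 10|b_IVW|, 20 se_IVW)`),
  widening tenfold up to five times if the optimum lands on an edge, and
  errors rather than returning an edge solution. The SE is
  $1/\sqrt{-\ell''(\hat\beta)}$ by central second difference with step
  $10^{-4}(1+|\hat\beta|)$.
- Extreme z-scores: two-sided p-values are floored at 1e-300 so that
  noise-free or enormous-n scenarios stay within the valid (0, 1] range
  instead of underflowing to 0.
- Clumping tie-breaks, report column order, and JSON serialisation
  digits are all fixed, so a rerun under the same configuration and seed
  is byte-identical on disk.
- Degenerate inputs fail loudly: zero exposure beta in a Wald ratio,
  collinear exposure effects in Egger, fewer than 3 usable variants for
  median/Egger, empty instrument sets, zero kept harmonised records.

## Validation scale

The test suite validates estimators against independent oracles
(weighted least squares via `lm()`, quantile root-finding, grid scans of
the profile likelihood) on small fixtures, and calibration by
simulation at the study's scale: 100 instruments, exposure GWAS of
3,636, binary outcome GWAS of $10^6$ with 4% cases, causal log-OR −0.04.
At 1000 seeded replicates: IVW 95% CI coverage 0.953, type-I error 0.048
under the null, and Egger-intercept coverage of zero 0.934 under
balanced pleiotropy (SD 0.005). The directional-pleiotropy recovery
check runs in a strong-instrument regime (exposure n = $10^7$) because
with weak instruments, orientation errors attenuate the Egger intercept
toward zero — a genuine property of the estimator, worth knowing when
reading real intercepts. The analysis scripts use 300-replicate working
versions of the same checks.

## Known limitations

MR-Egger with 3–4 instruments is reported but fragile, as the audit
columns make visible. The delta-method Wald SE understates uncertainty
for weak instruments (MR-RAPS is the estimator that models exposure
error). Proxy substitution trusts the proxy table's orientation claim.
No multiple-testing adjustment is applied across outcomes or methods —
nominal p-values are reported, matching standard practice for a small
set of prespecified outcomes. Non-linear and sex-stratified MR,
multivariable MR, MR-PRESSO and mode-based estimators are out of scope.
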