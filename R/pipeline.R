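#' Configuration for a full MR analysis run
#'
#' Bundles everything [mr_run()] needs: the exposure panel, one or more
#' outcome panels, selection thresholds (a primary tier and an optional
#' liberal tier), optional LD and proxy tables, estimator settings, and
#' power settings. Panels may be given as [trait_panel()] objects or as
#' specs `list(path=, trait_type=, column_map=, ...)` forwarded to
#' [read_panel()].
#'
#' @param exposure Exposure panel or read spec.
#' @param outcomes Named list of outcome panels or read specs.
#' @param selection Primary-tier [selection_params()].
#' @param liberal Optional liberal-tier [selection_params()] (e.g.
#'   p < 5e-6).
#' @param ld Optional [ld_table()].
#' @param proxies Optional proxy table (`variant_id`, `proxy_id`, `r2`).
#' @param estimator List: `bootstrap_reps` (weighted-median bootstrap,
#'   default 1000), `seed` (required when the weighted median runs),
#'   `effects_mode` for IVW (default `"auto"`).
#' @param power List: `r2_override` (instrument r-squared to use instead
#'   of the selected set's own total, e.g. an externally reported value),
#'   `alpha` (default 0.05), `target_power` (default 0.8).
#' @param maf_threshold Palindromic ambiguity window for harmonisation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(exposure, outcomes, selection = selection_params(),
                       liberal = NULL, ld = NULL, proxies = NULL,
                       estimator = list(), power = list(),
                       maf_threshold = 0.42) {
  as_panel <- function(x, id) {
    if (inherits(x, "trait_panel")) return(x)
    if (is.list(x) && !is.null(x$path)) {
      return(read_panel(x$path,
                        trait_type = x$trait_type %||% "continuous",
                        trait_id = x$trait_id %||% id,
                        column_map = x$column_map,
                        n_cases = x$n_cases, n_controls = x$n_controls))
    }
    stopf("panel '%s' must be a trait_panel or a list with a $path", id)
  }
  exposure <- as_panel(exposure, "exposure")
  if (length(outcomes) == 0L) stopf("at least one outcome is required")
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stopf("`outcomes` must be a named list")
  }
  outcomes <- Map(as_panel, outcomes, names(outcomes))
  estimator <- utils::modifyList(
    list(bootstrap_reps = 1000L, seed = NULL, effects_mode = "auto"),
    estimator
  )
  power <- utils::modifyList(
    list(r2_override = NULL, alpha = 0.05, target_power = 0.8),
    power
  )
  structure(
    list(exposure = exposure, outcomes = outcomes, selection = selection,
         liberal = liberal, ld = ld, proxies = proxies,
         estimator = estimator, power = power,
         maf_threshold = maf_threshold),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: `exposure:` and `outcomes:` blocks
#' with `path`, `trait_type`, and an optional `column_map` mapping
#' canonical column names to the file's names; `selection:`/`liberal:`
#' blocks with the threshold fields; optional `ld`/`proxies` TSV paths;
#' `estimator:` and `power:` blocks.
#'
#' @param path Path to a YAML file.
#' @param base_dir Directory against which relative file paths are
#'   resolved (default: the YAML's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base_dir, p)
  }
  fix_paths <- function(spec) {
    if (is.list(spec) && !is.null(spec$path)) spec$path <- resolve(spec$path)
    spec
  }
  sel <- function(block) {
    if (is.null(block)) NULL else do.call(selection_params, block)
  }
  run_config(
    exposure = fix_paths(y$exposure),
    outcomes = lapply(y$outcomes, fix_paths),
    selection = sel(y$selection) %||% selection_params(),
    liberal = sel(y$liberal),
    ld = if (!is.null(y$ld)) read_ld_table(resolve(y$ld)) else NULL,
    proxies = if (!is.null(y$proxies)) {
      read.delim(resolve(y$proxies), sep = "\t", stringsAsFactors = FALSE)
    } else NULL,
    estimator = y$estimator %||% list(),
    power = y$power %||% list(),
    maf_threshold = y$maf_threshold %||% 0.42
  )
}

# Case/control counts for a binary outcome panel: panel-level if given,
# else the per-record maximum.
panel_counts <- function(panel) {
  if (!is.null(panel$n_cases) && !is.null(panel$n_controls)) {
    return(list(n_cases = panel$n_cases, n_controls = panel$n_controls))
  }
  ca <- suppressWarnings(max(panel$records$n_cases, na.rm = TRUE))
  co <- suppressWarnings(max(panel$records$n_controls, na.rm = TRUE))
  if (!is.finite(ca) || !is.finite(co)) return(NULL)
  list(n_cases = ca, n_controls = co)
}

#' Run the full MR analysis
#'
#' Orchestrates, per selection tier (primary and, if configured, liberal)
#' and per outcome: instrument selection on the exposure panel
#' ([clump()]), outcome lookup with proxy substitution, harmonisation
#' ([harmonise_panels()]), estimation, and power. With one usable variant
#' only the Wald ratio is reported; with two, IVW and MR-RAPS are added;
#' with three or more, the weighted median and MR-Egger as well. Power
#' rows use each binary outcome's case/control counts with the instrument
#' set's variance explained (or `power$r2_override`). A failure in one
#' outcome is recorded as a structured error and does not abort the
#' others; the run is deterministic given the configuration and seed.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: list with `report` (data
#'   frame of estimator rows), `harmonisation` (audit log across
#'   outcomes/tiers), `instrument_qc`, `power`, `provenance`, and
#'   `errors`.
#' @export
mr_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tiers <- list(primary = config$selection)
  if (!is.null(config$liberal)) tiers$liberal <- config$liberal
  report <- list()
  logs <- list()
  qc <- list()
  power_rows <- list()
  errors <- list()

  for (tier in names(tiers)) {
    params <- tiers[[tier]]
    inst <- tryCatch(clump(config$exposure, config$ld, params),
                     error = function(e) e)
    if (inherits(inst, "error")) {
      errors[[length(errors) + 1L]] <- list(stage = "selection", tier = tier,
                                            message = conditionMessage(inst))
      next
    }
    qc[[tier]] <- data.frame(
      selection = tier, variant_id = names(inst$per_variant_f),
      f_statistic = unname(inst$per_variant_f), mean_f = inst$mean_f,
      r2_total = inst$r2_total, stringsAsFactors = FALSE
    )
    for (oid in names(config$outcomes)) {
      panel <- config$outcomes[[oid]]
      res <- tryCatch({
        h <- harmonise_panels(inst, panel, config$proxies, params,
                              maf_threshold = config$maf_threshold)
        hlog <- cbind(outcome_id = oid, selection = tier, as.data.frame(h))
        nk <- nrow(kept_records(h))
        ests <- list()
        if (nk == 1L) {
          wr <- wald_ratio(kept_records(h))
          ests$wald <- mr_result("Wald", 1L, wr$theta, wr$se)
        } else {
          ests$ivw <- mr_ivw(h, effects_mode = config$estimator$effects_mode)
          ests$raps <- mr_raps(h)
          if (nk >= 3L) {
            ests$wm <- mr_weighted_median(
              h, bootstrap_reps = config$estimator$bootstrap_reps,
              seed = config$estimator$seed %||%
                stopf("estimator seed required for the weighted median")
            )
            ests$egger <- mr_egger(h)
          }
        }
        rows <- do.call(rbind, lapply(ests, to_odds_scale, outcome_id = oid,
                                      trait_type = panel$trait_type,
                                      selection = tier))
        list(rows = rows, hlog = hlog)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(stage = "outcome", tier = tier,
                                              outcome_id = oid,
                                              message = conditionMessage(res))
        next
      }
      report[[length(report) + 1L]] <- res$rows
      logs[[length(logs) + 1L]] <- res$hlog
    }
    # Power per binary outcome, from its counts and the instrument r2.
    r2 <- config$power$r2_override %||% inst$r2_total
    if (!is.null(r2) && is.finite(r2)) {
      for (oid in names(config$outcomes)) {
        panel <- config$outcomes[[oid]]
        if (panel$trait_type != "binary") next
        counts <- panel_counts(panel)
        if (is.null(counts)) next
        q <- power_query(counts$n_cases, counts$n_controls, r2,
                         alpha = config$power$alpha,
                         target_power = config$power$target_power)
        dor <- detectable_or(q)
        power_rows[[length(power_rows) + 1L]] <- data.frame(
          outcome_id = oid, selection = tier,
          n_cases = counts$n_cases, n_controls = counts$n_controls,
          r2_instruments = r2, alpha = q$alpha,
          target_power = q$target_power,
          or_protective = unname(dor["or_protective"]),
          or_harmful = unname(dor["or_harmful"]),
          stringsAsFactors = FALSE
        )
      }
    }
  }

  if (length(report) == 0L && length(errors) > 0L) {
    stopf("all outcomes failed: %s",
          paste(vapply(errors, `[[`, "", "message"), collapse = "; "))
  }
  structure(
    list(
      report = do.call(rbind, report),
      harmonisation = if (length(logs)) do.call(rbind, logs) else NULL,
      instrument_qc = if (length(qc)) do.call(rbind, qc) else NULL,
      power = if (length(power_rows)) do.call(rbind, power_rows) else NULL,
      provenance = list(
        package_version = as.character(utils::packageVersion("summr")),
        seed = config$estimator$seed,
        config_hash = config_hash(config)
      ),
      errors = errors
    ),
    class = "run_report"
  )
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d estimator rows; %d error(s)\n",
              if (is.null(x$report)) 0L else nrow(x$report),
              length(x$errors)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write a run report to an output directory
#'
#' Writes `report.tsv` and `report.json` (full report, deterministic
#' serialisation), `harmonisation_log.tsv`, `instrument_qc.tsv`, and
#' `power.tsv`.
#'
#' @param report A `run_report` from [mr_run()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$report)) {
    write_report(report$report, file.path(dir, "report.tsv"))
  }
  if (!is.null(report$harmonisation)) {
    write_harmonisation_log(report$harmonisation,
                            file.path(dir, "harmonisation_log.tsv"))
  }
  for (part in c("instrument_qc", "power")) {
    if (!is.null(report[[part]])) {
      write.table(report[[part]], file.path(dir, paste0(part, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    }
  }
  json <- jsonlite::toJSON(unclass(report), dataframe = "rows",
                           auto_unbox = TRUE, digits = 10, na = "null",
                           null = "null")
  writeLines(json, file.path(dir, "report.json"))
  invisible(dir)
}

#' Simulation study: estimator calibration under a known truth
#'
#' Repeatedly generates two-sample GWAS panels from `sim`, applies the
#' estimators to all variants (bypassing selection and corruption), and
#' summarises recovery of the true causal effect: mean bias, empirical
#' and mean estimated SE, 95% CI coverage, and rejection rate at `alpha`
#' (the type-I error when `sim$true_beta = 0`). For MR-Egger the coverage
#' of the pleiotropy mean by the intercept CI is also reported. Replicate
#' r uses seed `sim$seed + r`, so results are reproducible and
#' replicate-level parallelisable.
#'
#' @param sim A [sim_config()].
#' @param replicates Number of replicates (>= 1).
#' @param methods Subset of `c("ivw", "weighted_median", "egger",
#'   "raps")`.
#' @param wm_reps Bootstrap resamples per replicate for the weighted
#'   median (kept modest; the bootstrap is the dominant cost).
#' @param alpha Test level for rejection rates.
#' @param effects_mode IVW variance model (default `"auto"`).
#' @return Data frame, one row per estimator.
#' @export
simulate_and_recover <- function(sim, replicates,
                                 methods = c("ivw", "egger"),
                                 wm_reps = 200L, alpha = 0.05,
                                 effects_mode = "auto") {
  stopifnot(inherits(sim, "sim_config"), replicates >= 1)
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger", "raps"),
                       several.ok = TRUE)
  z <- z_ci(alpha)
  acc <- list()
  record <- function(method, r, est, truth_beta, intercept_truth = NA) {
    acc[[length(acc) + 1L]] <<- data.frame(
      method = method, rep = r, beta = est$beta, se = est$se,
      cover = est$ci_low <= truth_beta & truth_beta <= est$ci_high,
      reject = est$pval < alpha,
      intercept_cover = if (is.finite(est$intercept)) {
        abs(est$intercept - intercept_truth) <= z * est$intercept_se
      } else NA,
      stringsAsFactors = FALSE
    )
  }
  for (r in seq_len(replicates)) {
    cfg <- sim
    cfg$seed <- sim$seed + r
    dat <- generate_two_sample(cfg)
    hs <- as_harmonised(dat$exposure, dat$outcome)
    if ("ivw" %in% methods) {
      record("ivw", r, mr_ivw(hs, effects_mode = effects_mode),
             sim$true_beta)
    }
    if ("egger" %in% methods) {
      record("egger", r, mr_egger(hs), sim$true_beta, sim$pleiotropy_mean)
    }
    if ("weighted_median" %in% methods) {
      record("weighted_median", r,
             mr_weighted_median(hs, bootstrap_reps = wm_reps,
                                seed = cfg$seed + 500000L),
             sim$true_beta)
    }
    if ("raps" %in% methods) {
      record("raps", r, mr_raps(hs), sim$true_beta)
    }
  }
  long <- do.call(rbind, acc)
  out <- do.call(rbind, lapply(split(long, long$method), function(d) {
    data.frame(
      method = d$method[1L], replicates = nrow(d),
      mean_bias = mean(d$beta) - sim$true_beta,
      empirical_se = sd(d$beta), mean_se = mean(d$se),
      coverage = mean(d$cover), rejection_rate = mean(d$reject),
      intercept_coverage = mean(d$intercept_cover),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
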