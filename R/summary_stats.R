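#' Canonical summary-statistic columns
#'
#' Column names used internally for all GWAS summary statistics. Foreign
#' header dialects (for example the COVID-19 Host Genetics Initiative
#' round-6 headers) are mapped onto these names at read time via the
#' `column_map` argument of [read_panel()]; everything downstream sees only
#' this schema.
#'
#' @format A character vector of canonical column names.
#' @export
CANONICAL_COLUMNS <- c(
  "variant_id", "chromosome", "position", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n", "n_cases", "n_controls"
)

REQUIRED_COLUMNS <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

VALID_ALLELES <- c("A", "C", "G", "T")

# Validate and normalise a data frame of association records: upper-case
# alleles, enforce se > 0, distinct alleles, p in (0,1], and
# n = n_cases + n_controls where all three are present. Missing EAF stays NA.
as_association_records <- function(df, source = "records") {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stopf("%s: missing required column(s): %s", source,
          paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(CANONICAL_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, CANONICAL_COLUMNS]

  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("n", "n_cases", "n_controls")) df[[col]] <- as.double(df[[col]])

  bad_allele <- !(df$effect_allele %in% VALID_ALLELES) |
    !(df$other_allele %in% VALID_ALLELES)
  if (any(bad_allele)) {
    stopf("%s: non-ACGT alleles for variant(s): %s", source,
          paste(df$variant_id[bad_allele], collapse = ", "))
  }
  same_allele <- df$effect_allele == df$other_allele
  if (any(same_allele)) {
    stopf("%s: effect and other allele identical for variant(s): %s", source,
          paste(df$variant_id[same_allele], collapse = ", "))
  }
  bad_se <- is.na(df$se) | df$se <= 0
  if (any(bad_se)) {
    stopf("%s: non-positive or missing standard error for variant(s): %s",
          source, paste(df$variant_id[bad_se], collapse = ", "))
  }
  # p-values are recomputable from beta/se; fill where absent, guarding
  # against underflow for extreme z-scores.
  no_p <- is.na(df$pval)
  df$pval[no_p] <- two_sided_p(df$beta[no_p] / df$se[no_p])
  bad_p <- df$pval <= 0 | df$pval > 1
  if (any(bad_p)) {
    stopf("%s: p-value outside (0, 1] for variant(s): %s", source,
          paste(df$variant_id[bad_p], collapse = ", "))
  }
  has_counts <- !is.na(df$n_cases) & !is.na(df$n_controls)
  fill_n <- has_counts & is.na(df$n)
  df$n[fill_n] <- df$n_cases[fill_n] + df$n_controls[fill_n]
  bad_n <- has_counts & !is.na(df$n) &
    abs(df$n - (df$n_cases + df$n_controls)) > 0.5
  if (any(bad_n)) {
    stopf("%s: n != n_cases + n_controls for variant(s): %s", source,
          paste(df$variant_id[bad_n], collapse = ", "))
  }
  dup <- duplicated(df$variant_id)
  if (any(dup)) {
    stopf("%s: duplicated variant_id(s): %s", source,
          paste(unique(df$variant_id[dup]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Construct a trait panel
#'
#' A trait panel is the package's container for one trait's GWAS summary
#' statistics: a validated data frame of per-variant association records
#' keyed by `variant_id`, plus trait-level metadata.
#'
#' @param records Data frame with (at least) the required canonical columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`; optional
#'   `chromosome`, `position`, `eaf`, `pval`, `n`, `n_cases`, `n_controls`.
#'   Betas are log odds ratios for binary traits and per-SD effects for
#'   standardised continuous traits.
#' @param trait_id Short identifier for the trait.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param n_cases,n_controls Optional panel-level case/control counts for
#'   binary traits (used when per-record counts are absent).
#' @return An object of class `trait_panel`.
#' @export
trait_panel <- function(records, trait_id, trait_type = c("continuous", "binary"),
                        n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (!is_string(trait_id)) stopf("`trait_id` must be a single string")
  records <- as_association_records(as.data.frame(records),
                                    source = sprintf("panel '%s'", trait_id))
  if (trait_type == "binary") {
    has_record_counts <- any(!is.na(records$n_cases) & !is.na(records$n_controls))
    has_panel_counts <- !is.null(n_cases) && !is.null(n_controls)
    if (!has_record_counts && !has_panel_counts) {
      stopf("binary panel '%s' requires case/control counts on at least one record or at panel level",
            trait_id)
    }
  }
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         n_cases = n_cases, n_controls = n_controls),
    class = "trait_panel"
  )
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf("<trait_panel> %s (%s): %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  invisible(x)
}

# Look up one variant's record; returns a one-row data frame or NULL.
panel_record <- function(panel, variant_id) {
  i <- match(variant_id, panel$records$variant_id)
  if (is.na(i)) NULL else panel$records[i, , drop = FALSE]
}

#' Read a GWAS summary-statistic panel from delimited text
#'
#' Reads a tab-delimited file with a header row into a [trait_panel()].
#' Files in foreign dialects are adapted via `column_map`, a named list or
#' vector mapping canonical column names (see [CANONICAL_COLUMNS]) to the
#' file's column names; canonical names not listed in the map are looked up
#' verbatim. Alleles are upper-cased; a missing effect-allele frequency is
#' preserved as `NA` (distinct from any numeric value); rows with
#' non-positive standard errors are rejected with an error naming the
#' offending variants.
#'
#' @param path Path to a delimited text file with a header row.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param trait_id Trait identifier; defaults to the file name.
#' @param column_map Named list/vector, canonical name -> file column name.
#' @param sep Field separator (default tab).
#' @param n_cases,n_controls Optional panel-level counts, passed to
#'   [trait_panel()].
#' @return A `trait_panel`.
#' @export
read_panel <- function(path, trait_type = c("continuous", "binary"),
                       trait_id = NULL, column_map = NULL, sep = "\t",
                       n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  trait_id <- trait_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), CANONICAL_COLUMNS)
    if (length(unknown) > 0L) {
      stopf("column_map keys must be canonical column names; unknown: %s",
            paste(unknown, collapse = ", "))
    }
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0L) {
      stopf("file '%s' lacks mapped column(s): %s", path,
            paste(absent, collapse = ", "))
    }
    for (canon in names(column_map)) {
      raw[[canon]] <- raw[[column_map[[canon]]]]
    }
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_req) > 0L) {
    stopf("file '%s' lacks required column(s): %s (map them via column_map)",
          path, paste(missing_req, collapse = ", "))
  }
  trait_panel(raw[, intersect(CANONICAL_COLUMNS, names(raw)), drop = FALSE],
              trait_id = trait_id, trait_type = trait_type,
              n_cases = n_cases, n_controls = n_controls)
}

#' Write a trait panel to tab-delimited text
#'
#' @param panel A [trait_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "trait_panel"))
  write.table(panel$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

REPORT_COLUMNS <- c(
  "outcome_id", "selection", "method", "n_snp", "beta", "se",
  "or_", "ci_low", "ci_high", "pval",
  "egger_intercept", "intercept_se", "intercept_p"
)

# Normalise a data frame of report rows to the stable column order.
as_report_rows <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stopf("report is empty: no rows to write")
  for (col in setdiff(REPORT_COLUMNS, names(rows))) rows[[col]] <- NA
  rows <- rows[, REPORT_COLUMNS]
  rows$method <- as.character(rows$method)
  rows$outcome_id <- as.character(rows$outcome_id)
  rows$selection <- as.character(rows$selection)
  rows$n_snp <- as.integer(rows$n_snp)
  num <- setdiff(REPORT_COLUMNS, c("outcome_id", "selection", "method", "n_snp"))
  for (col in num) rows[[col]] <- as.numeric(rows[[col]])
  rownames(rows) <- NULL
  rows
}

#' Write an MR report table
#'
#' Writes estimator results (one row per outcome x method, mirroring a
#' typical MR results table) as tab-delimited text with a stable column
#' order. Numeric fields are written with enough digits to round-trip
#' through [read_report()] losslessly at 6 significant figures; the
#' MR-Egger intercept columns are populated only on Egger rows.
#'
#' @param rows Data frame of report rows (see [to_odds_scale()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  rows <- as_report_rows(rows)
  out <- rows
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("n_snp"))
  for (col in names(out)[num]) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 10, format = "g"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an MR report table written by [write_report()]
#'
#' @param path Path to a report TSV.
#' @return Data frame of report rows in the stable column order.
#' @export
read_report <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  as_report_rows(df)
}
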