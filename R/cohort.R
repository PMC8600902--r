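#' Validate and class a per-patient cohort table
#'
#' A cohort table has one row per patient with columns
#' `patient_id`, `cohort` (one of `training`, `internal_validation`,
#' `external_validation`), `dfs_months` (disease-free survival in months),
#' `event` (1 = recurrence/death observed, 0 = censored), the eight TACS
#' indicator columns `tacs_1`..`tacs_8`, and optionally clinical covariate
#' columns, per-patient TCMF feature columns and precomputed score columns
#' (e.g. `tcmf_score`, `tacs_score`, `cli_score`).
#'
#' @param df a data.frame.
#' @return `df` with class `cohort_table` prepended, after validation.
#' @export
as_cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("patient_id", "cohort", "dfs_months", "event",
           paste0("tacs_", 1:8))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_row <- function(what, rows) {
    stop(sprintf("cohort table: %s in row(s) %s", what,
                 paste(rows, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(df$patient_id)
  if (any(dup)) bad_row("duplicate patient_id", which(dup))
  valid_cohorts <- c("training", "internal_validation", "external_validation")
  bad <- which(!df$cohort %in% valid_cohorts)
  if (length(bad)) bad_row("unknown cohort label", bad)
  bad <- which(!is.finite(df$dfs_months) | df$dfs_months < 0)
  if (length(bad)) bad_row("negative or non-numeric dfs_months", bad)
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad)) bad_row("event flag outside {0,1}", bad)
  for (k in paste0("tacs_", 1:8)) {
    bad <- which(!is.finite(df[[k]]))
    if (length(bad)) bad_row(sprintf("non-numeric %s", k), bad)
  }
  df$patient_id <- as.character(df$patient_id)
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read a cohort CSV
#'
#' @param path path to a CSV file with the header described in
#'   [as_cohort_table()].
#' @return A validated `cohort_table`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: '%s'", path), call. = FALSE)
  as_cohort_table(read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE))
}

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# columns of `table` holding TCMF features, in registry order
tcmf_columns <- function(table, registry = tcmf_registry()) {
  present <- registry[registry %in% names(table)]
  present
}
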