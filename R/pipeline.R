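# Patient-level aggregation and training-cohort Z-score normalization.
# Order is fixed: per-ROI vectors are averaged per patient first, then the
# aggregated features are Z-scored with training-cohort statistics.

#' Average TCMF vectors over a patient's ROIs
#'
#' Elementwise arithmetic mean with uniform ROI weighting.
#'
#' @param vectors a list of named TCMF vectors (or a matrix with one ROI per
#'   row) sharing the same feature registry.
#' @return Named numeric vector: the per-patient mean TCMF vector.
#' @export
aggregate_patient <- function(vectors) {
  if (is.matrix(vectors)) vectors <- asplit(vectors, 1)
  if (!length(vectors))
    stop("cannot aggregate zero ROIs; exclude the patient upstream",
         call. = FALSE)
  nm <- names(vectors[[1]])
  for (v in vectors)
    if (!identical(names(v), nm))
      stop("ROI vectors do not share one feature registry", call. = FALSE)
  colMeans(do.call(rbind, vectors))
}

#' Fit / apply training-cohort Z-score normalization
#'
#' `fit_normalizer` estimates per-feature mean and sample standard deviation
#' from the rows labeled `training` only; `apply_normalizer` transforms any
#' cohort with the stored parameters (no refitting, so distribution shifts
#' in validation cohorts are preserved). Features with zero training
#' variance are dropped with a warning.
#'
#' @param table a `cohort_table` whose rows carry aggregated TCMF columns.
#' @param features feature columns to normalize; defaults to the registry
#'   columns present in the table.
#' @return `fit_normalizer`: an object of class `tcmf_normalizer` with
#'   fields `mean`, `sd` (named vectors) and `dropped` (zero-variance
#'   feature names). `apply_normalizer`: the table with normalized feature
#'   columns (dropped features removed).
#' @export
fit_normalizer <- function(table, features = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (is.null(features)) features <- tcmf_columns(table)
  if (!length(features))
    stop("no feature columns found to normalize", call. = FALSE)
  tr <- table[table$cohort == "training", features, drop = FALSE]
  if (!nrow(tr)) stop("no training rows to fit the normalizer on",
                      call. = FALSE)
  mu <- vapply(tr, mean, numeric(1))
  sdv <- vapply(tr, sd, numeric(1))
  dropped <- names(sdv)[!is.finite(sdv) | sdv == 0]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) " ..." else "")
  keep <- setdiff(features, dropped)
  structure(list(mean = mu[keep], sd = sdv[keep], dropped = dropped),
            class = "tcmf_normalizer")
}

#' @rdname fit_normalizer
#' @param params a `tcmf_normalizer` from `fit_normalizer`.
#' @export
apply_normalizer <- function(params, table) {
  stopifnot(inherits(params, "tcmf_normalizer"))
  feats <- names(params$mean)
  missing_f <- setdiff(feats, names(table))
  if (length(missing_f))
    stop("table lacks normalizer feature(s): ",
         paste(head(missing_f, 5), collapse = ", "), call. = FALSE)
  for (f in feats) table[[f]] <- (table[[f]] - params$mean[f]) / params$sd[f]
  table[setdiff(names(table), params$dropped)]
}

#' Extract and aggregate TCMFs for a set of patients
#'
#' Convenience driver: runs [extract_tcmf()] on every ROI image, averages
#' per patient with [aggregate_patient()], and returns one row per patient.
#' Patients whose ROIs yield no collagen at all are still returned (their
#' morphological features carry the empty-network sentinels).
#'
#' @param rois named list: one entry per patient, each a list of
#'   [shg_image()] ROIs.
#' @param config a [tacs_config()].
#' @return data.frame with `patient_id` and the 142 TCMF columns.
#' @export
extract_patient_features <- function(rois, config = tacs_config()) {
  stopifnot(is.list(rois), !is.null(names(rois)))
  rows <- lapply(names(rois), function(pid) {
    vs <- lapply(rois[[pid]], extract_tcmf, config = config)
    c(patient_id = pid, as.list(aggregate_patient(vs)))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df
}
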