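#' Pipeline configuration
#'
#' Collects every tunable of the extraction, scoring and evaluation stages
#' with its documented default. The configuration is a flat named list and
#' serializes to/from a plain text file (one `key: value` per line, DCF
#' format), so a run can be reproduced from its logged configuration.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list of class `tacs_config`.
#' @section Defaults:
#' \describe{
#'   \item{pixel_size_um (0.29297)}{pixel edge in um; 512 px spans 150 um.}
#'   \item{segmentation_method ("otsu")}{collagen threshold criterion.}
#'   \item{smooth_sigma_px (1)}{Gaussian pre-smoothing sd in pixels.}
#'   \item{min_spur_um (3)}{skeleton spurs shorter than this are pruned.}
#'   \item{min_fiber_um (5)}{traced fibers shorter than this are dropped.}
#'   \item{continuation_deg (20)}{max tangent difference to join fibers
#'     across a crosslink.}
#'   \item{glcm_levels (16)}{gray-level quantization for co-occurrence.}
#'   \item{glcm_displacements (1:5)}{pixel displacements.}
#'   \item{glcm_angles (c(0,45,90,135))}{co-occurrence directions, degrees.}
#'   \item{gabor_frequencies (c(0.05,0.1,0.2,0.4))}{cycles/pixel.}
#'   \item{gabor_angles (seq(0,150,30))}{filter orientations, degrees.}
#'   \item{texture_masked (FALSE)}{compute texture on the raw ROI (default)
#'     or masked to collagen pixels.}
#'   \item{cv_folds (10)}{cross-validation folds for penalized Cox fits.}
#'   \item{lambda_rule ("1se")}{penalty choice, "1se" or "min".}
#'   \item{roc_horizon_months (60)}{horizon for 5-year ROC analyses.}
#'   \item{bootstrap_reps (1000)}{bootstrap replicates for AUC CIs.}
#'   \item{calibration_reps (200)}{bootstrap replicates for calibration.}
#'   \item{seed (1)}{default random seed, logged with every run.}
#' }
#' @examples
#' cfg <- tacs_config(glcm_levels = 8)
#' cfg$glcm_levels
#' @export
tacs_config <- function(...) {
  defaults <- list(
    pixel_size_um = 150 / 512,
    segmentation_method = "otsu",
    smooth_sigma_px = 1,
    min_spur_um = 3,
    min_fiber_um = 5,
    continuation_deg = 20,
    glcm_levels = 16L,
    glcm_displacements = 1:5,
    glcm_angles = c(0, 45, 90, 135),
    gabor_frequencies = c(0.05, 0.1, 0.2, 0.4),
    gabor_angles = seq(0, 150, by = 30),
    texture_masked = FALSE,
    cv_folds = 10L,
    lambda_rule = "1se",
    roc_horizon_months = 60,
    bootstrap_reps = 1000L,
    calibration_reps = 200L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(defaults, over)
  if (!cfg$lambda_rule %in% c("1se", "min"))
    stop("lambda_rule must be '1se' or 'min'", call. = FALSE)
  structure(cfg, class = "tacs_config")
}

#' Write / read a configuration file
#'
#' Flat text serialization of a [tacs_config()]; vector values are
#' comma-separated.
#'
#' @param config a `tacs_config`.
#' @param path file path.
#' @return `read_config` returns a `tacs_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tacs_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  parsed <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else
      if (identical(parts, "TRUE") || identical(parts, "FALSE"))
        as.logical(parts) else parts
  })
  names(parsed) <- keys
  do.call(tacs_config, parsed)
}
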