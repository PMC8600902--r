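#' Morphological collagen features of a fiber network
#'
#' Computes the eight morphological features of the TCMF panel from a traced
#' [extract_fiber_network()] result:
#' \describe{
#'   \item{morph_area_fraction}{collagen mask pixels / total pixels.}
#'   \item{morph_fiber_count}{number of traced fibers in the ROI.}
#'   \item{morph_mean_length}{mean fiber arc length (um).}
#'   \item{morph_mean_width}{fiber width (um): twice the Euclidean distance
#'     transform of the mask sampled along skeleton pixels, minus one pixel
#'     (the distance transform of a w-px stroke reads (w+1)/2 at its
#'     centerline).}
#'   \item{morph_straightness}{mean endpoint chord / arc length, in (0, 1].}
#'   \item{morph_crosslink_density}{crosslinks per 100 um^2 of collagen.}
#'   \item{morph_crosslink_space}{mean skeleton path length (um) between
#'     adjacent crosslinks; segments not bounded by two distinct crosslinks
#'     are excluded.}
#'   \item{morph_orientation_concentration}{length of the mean resultant
#'     vector of doubled fiber chord angles (axial statistics): 1 when all
#'     fibers share one orientation, near 0 for isotropic networks.}
#' }
#' An empty network returns 0 for every feature by convention, so that
#' downstream Z-scoring never propagates non-finite values.
#'
#' @param network a `fiber_network`.
#' @return Named numeric vector of length 8, names as above.
#' @export
compute_morph_features <- function(network) {
  stopifnot(inherits(network, "fiber_network"))
  psz <- network$pixel_size_um
  out <- setNames(numeric(8), c(
    "morph_area_fraction", "morph_fiber_count", "morph_mean_length",
    "morph_mean_width", "morph_straightness", "morph_crosslink_density",
    "morph_crosslink_space", "morph_orientation_concentration"))
  out["morph_area_fraction"] <- mean(network$mask)
  nf <- length(network$fibers)
  out["morph_fiber_count"] <- nf
  if (nf > 0) {
    seg_len <- function(p)
      sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
    lens_px <- vapply(network$fibers, seg_len, numeric(1))
    chords_px <- vapply(network$fibers, function(p)
      sqrt(sum((p[nrow(p), ] - p[1, ])^2)), numeric(1))
    out["morph_mean_length"] <- mean(lens_px) * psz
    out["morph_straightness"] <- mean(ifelse(lens_px > 0,
                                             pmin(1, chords_px / lens_px), 1))
    ang2 <- vapply(network$fibers, function(p) {
      d <- p[nrow(p), ] - p[1, ]                 # (drow, dcol)
      2 * axial_angle_deg(d[2], d[1]) * pi / 180
    }, numeric(1))
    out["morph_orientation_concentration"] <-
      sqrt(mean(cos(ang2))^2 + mean(sin(ang2))^2)
  }
  if (any(network$skeleton)) {
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(network$mask * 1)))
    w_px <- 2 * mean(dm[network$skeleton]) - 1
    out["morph_mean_width"] <- max(0, w_px) * psz
  }
  n_cross <- nrow(network$crosslinks)
  mask_area_um2 <- sum(network$mask) * psz^2
  if (n_cross > 0 && mask_area_um2 > 0)
    out["morph_crosslink_density"] <- n_cross / (mask_area_um2 / 100)
  if (length(network$link_spans_um))
    out["morph_crosslink_space"] <- mean(network$link_spans_um)
  out
}
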