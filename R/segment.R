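#' Segment collagen from an SHG image
#'
#' Default method: light Gaussian smoothing followed by a global threshold
#' chosen by Otsu's between-class-variance criterion. Deterministic for
#' fixed parameters.
#'
#' @param image an [shg_image()].
#' @param method only `"otsu"` is currently implemented.
#' @param smooth_sigma_px Gaussian pre-smoothing sd in pixels (0 disables).
#' @return Logical matrix of the same shape as the image, TRUE on collagen.
#'   An all-zero image yields an all-FALSE mask; a constant positive image
#'   has no definable threshold and raises a degenerate-input error.
#' @export
segment_collagen <- function(image, method = "otsu", smooth_sigma_px = 1) {
  stopifnot(inherits(image, "shg_image"))
  method <- match.arg(method, "otsu")
  px <- image$pixels
  if (diff(range(px)) == 0) {
    if (px[1] == 0) return(matrix(FALSE, nrow(px), ncol(px)))
    stop("degenerate input: constant image, threshold undefined",
         call. = FALSE)
  }
  maxv <- 2^image$bit_depth - 1
  im <- EBImage::Image(px / maxv)
  if (smooth_sigma_px > 0) im <- EBImage::gblur(im, sigma = smooth_sigma_px)
  th <- EBImage::otsu(im, range = c(0, 1), levels = 2^image$bit_depth)
  m <- EBImage::imageData(im) > th
  matrix(as.logical(m), nrow(px), ncol(px))
}
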