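#' Construct an SHG image object
#'
#' An `shg_image` holds a single-channel second-harmonic-generation (SHG)
#' intensity grid together with its physical pixel size. Intensities are on
#' the native integer scale of the acquisition bit depth (0..255 for 8-bit,
#' 0..65535 for 16-bit). Pixel coordinates are 0-based, row-major with the
#' origin at the top-left; orientations are measured counter-clockwise from
#' the +x (column) axis in degrees on [0, 180).
#'
#' @param pixels numeric matrix of non-negative finite intensities, at least
#'   16 pixels per side.
#' @param pixel_size_um physical edge length of one pixel in micrometres
#'   (must be > 0). The default maps a 512x512 grid onto a 150 um x 150 um
#'   field of view.
#' @param id ROI identifier string.
#' @param bit_depth acquisition bit depth, 8 or 16.
#' @return An object of class `shg_image` with fields `pixels`,
#'   `pixel_size_um`, `id`, `bit_depth`.
#' @examples
#' img <- shg_image(matrix(0, 32, 32), pixel_size_um = 0.5, id = "roi1")
#' dim(img$pixels)
#' @export
shg_image <- function(pixels, pixel_size_um = 150 / 512, id = "roi",
                      bit_depth = 8) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (any(dim(pixels) < 16))
    stop("SHG image must have at least 16 pixels per side", call. = FALSE)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         id = as.character(id), bit_depth = as.integer(bit_depth)),
    class = "shg_image"
  )
}

#' @export
print.shg_image <- function(x, ...) {
  cat(sprintf("<shg_image '%s'> %d x %d px, %.4f um/px (%.1f x %.1f um), %d-bit\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um, x$bit_depth))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale SHG TIFF
#'
#' Reads a single-plane grayscale 8- or 16-bit TIFF into an [shg_image()].
#' Intensities are returned exactly as stored (native integer scale, no
#' rescaling).
#'
#' @param path path to the TIFF file.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param id ROI identifier; defaults to the file name without extension.
#' @return An `shg_image`.
#' @seealso [write_shg_image()]
#' @export
read_shg_image <- function(path, pixel_size_um = 150 / 512, id = NULL) {
  if (!file.exists(path))
    stop(sprintf("SHG image file not found: '%s'", path), call. = FALSE)
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] > 1)
      stop(sprintf("'%s' is multi-channel (%d channels); expected grayscale",
                   path, dim(raw)[3]), call. = FALSE)
    raw <- raw[, , 1]
  }
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stop(sprintf("unsupported bit depth %d in '%s'", bits, path), call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  shg_image(matrix(as.numeric(raw), nrow(raw), ncol(raw)),
            pixel_size_um = pixel_size_um, id = id, bit_depth = as.integer(bits))
}

#' Write an SHG image to a grayscale TIFF
#'
#' Writes the image at its native bit depth. A write/read round trip through
#' [read_shg_image()] reproduces the pixel grid bitwise (intensities are
#' integers on the native scale).
#'
#' @param image an `shg_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shg_image <- function(image, path) {
  stopifnot(inherits(image, "shg_image"))
  maxv <- 2^image$bit_depth - 1
  px <- image$pixels
  if (any(px > maxv))
    stop("intensities exceed the image bit depth", call. = FALSE)
  tiff::writeTIFF(px / maxv, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

# axial angle in degrees on [0,180): direction (dx, dy) with dy in row units
# (screen y grows downward, so CCW-from-+x means negating dy)
axial_angle_deg <- function(dx, dy) {
  a <- atan2(-dy, dx) * 180 / pi
  a %% 180
}
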