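# 134 textural features: 6 first-order histogram features, 80 gray-level
# co-occurrence features (4 statistics x 5 displacements x 4 directions)
# and 48 Gabor features (4 frequencies x 6 orientations x {mean, sd}).

#' First-order intensity histogram features
#'
#' Six statistics of the normalized 256-bin intensity histogram over the
#' image's bit-depth range: mean, variance (population), skewness, kurtosis
#' (excess-free, i.e. normal = 3), energy (sum p^2) and entropy
#' (-sum p log2 p). For 8-bit images each bin is one integer intensity, so
#' the histogram moments equal exact pixel moments. A zero-variance image
#' returns skewness and kurtosis 0 by convention.
#'
#' @param image an [shg_image()].
#' @return Named numeric vector of length 6
#'   (`hist_mean`, `hist_variance`, `hist_skewness`, `hist_kurtosis`,
#'   `hist_energy`, `hist_entropy`).
#' @export
histogram_features <- function(image) {
  stopifnot(inherits(image, "shg_image"))
  maxv <- 2^image$bit_depth - 1
  nb <- 256L
  width <- (maxv + 1) / nb
  bin <- pmin(nb - 1L, floor(image$pixels / width))   # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = nb)
  p <- counts / sum(counts)
  centers <- (seq_len(nb) - 1) * width + (width - 1) / 2
  mu <- sum(p * centers)
  v <- sum(p * (centers - mu)^2)
  skw <- if (v > 0) sum(p * (centers - mu)^3) / v^1.5 else 0
  krt <- if (v > 0) sum(p * (centers - mu)^4) / v^2 else 0
  nz <- p[p > 0]
  c(hist_mean = mu, hist_variance = v, hist_skewness = skw,
    hist_kurtosis = krt, hist_energy = sum(p^2),
    hist_entropy = -sum(nz * log2(nz)))
}

# offset (drow, dcol) for displacement d and direction angle (deg, CCW from
# +x with screen rows growing downward)
glcm_offset <- function(d, angle) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("GLCM direction must be one of 0, 45, 90, 135 degrees",
              call. = FALSE))
}

# symmetric normalized co-occurrence matrix for quantized image `q`
# (integer levels 1..levels)
glcm_matrix <- function(q, levels, d, angle) {
  off <- glcm_offset(d, angle)
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate(a + (b - 1L) * levels, nbins = levels * levels)
  m <- matrix(counts, levels, levels)
  m <- m + t(m)                      # symmetric accumulation
  m / sum(m)
}

glcm_stats <- function(p) {
  levels <- nrow(p)
  i <- matrix(seq_len(levels), levels, levels)
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + (i - j)^2))
  pi_ <- rowSums(p)
  mu_i <- sum(seq_len(levels) * pi_)
  sd_i <- sqrt(sum((seq_len(levels) - mu_i)^2 * pi_))
  correlation <- if (sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * p) / sd_i^2 else 0
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' Gray-level co-occurrence matrix (GLCM) texture features
#'
#' Quantizes the image to `levels` gray levels (uniform over the observed
#' min-max range), builds a symmetric normalized co-occurrence matrix for
#' every displacement/direction pair, and emits four statistics per matrix:
#' contrast, correlation, energy and homogeneity. With the defaults
#' (5 displacements x 4 directions) this yields 80 features named
#' `glcm_<stat>_d<displacement>_a<angle>`.
#'
#' A constant image quantizes to a single level: contrast 0, energy 1,
#' homogeneity 1 and correlation 0 (zero-variance convention).
#'
#' @param image an [shg_image()].
#' @param displacements integer pixel displacements (default 1:5).
#' @param angles directions in degrees, subset of {0, 45, 90, 135}.
#' @param levels number of quantization levels (default 16).
#' @return Named numeric vector (length 4 x displacements x angles).
#' @export
glcm_features <- function(image, displacements = 1:5,
                          angles = c(0, 45, 90, 135), levels = 16L) {
  stopifnot(inherits(image, "shg_image"))
  px <- image$pixels
  if (max(displacements) >= min(dim(px)))
    stop("image smaller than the maximum GLCM displacement", call. = FALSE)
  rng <- range(px)
  q <- if (diff(rng) == 0) matrix(1L, nrow(px), ncol(px)) else
    matrix(pmin(levels, 1L + floor((px - rng[1]) / diff(rng) * levels)),
           nrow(px), ncol(px))
  storage.mode(q) <- "integer"
  out <- numeric(0)
  for (d in displacements) for (a in angles) {
    st <- glcm_stats(glcm_matrix(q, levels, as.integer(d), a))
    names(st) <- sprintf("glcm_%s_d%d_a%d", names(st), d, a)
    out <- c(out, st)
  }
  out
}

# complex Gabor kernel; frequency in cycles/px, theta in degrees, one-octave
# bandwidth; the real part is DC-corrected so constant inputs respond ~0
gabor_kernel <- function(frequency, theta_deg, gamma = 1, max_half = Inf) {
  sigma <- sqrt(log(2) / 2) / (pi * frequency) * 3   # 1-octave bandwidth
  half <- min(max(3L, ceiling(3 * sigma)), max_half)
  xs <- -half:half
  rr <- matrix(xs, length(xs), length(xs))           # row offsets (y down)
  cc <- t(rr)                                        # column offsets (x)
  th <- theta_deg * pi / 180
  # angle measured CCW from +x with screen y growing downward
  xr <- cc * cos(th) - rr * sin(th)
  yr <- cc * sin(th) + rr * cos(th)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * frequency * xr)
  im <- env * sin(2 * pi * frequency * xr)
  re <- re - env * sum(re) / sum(env)     # zero the DC response
  list(re = re, im = im)
}

#' Gabor filter-bank texture features
#'
#' Convolves the image with a bank of complex Gabor filters (one-octave
#' bandwidth) and returns the mean and standard deviation of the magnitude
#' response per filter. With the defaults (4 frequencies x 6 orientations)
#' this yields 48 features named `gabor_f<frequency>_a<angle>_<mean|sd>`.
#' Filters are DC-corrected, so a constant image gives (near-)zero response.
#'
#' @param image an [shg_image()].
#' @param frequencies cycles/pixel, all below the Nyquist limit 0.5.
#' @param angles orientations in degrees.
#' @return Named numeric vector (length 2 x frequencies x angles).
#' @export
gabor_features <- function(image, frequencies = c(0.05, 0.1, 0.2, 0.4),
                           angles = seq(0, 150, by = 30)) {
  stopifnot(inherits(image, "shg_image"))
  if (any(frequencies >= 0.5))
    stop("Gabor frequency at or above Nyquist (0.5 cycles/pixel)",
         call. = FALSE)
  im <- EBImage::Image(image$pixels / (2^image$bit_depth - 1))
  max_half <- (min(dim(image$pixels)) - 1L) %/% 2L   # kernel must fit image
  out <- numeric(0)
  for (f in frequencies) for (a in angles) {
    k <- gabor_kernel(f, a, max_half = max_half)
    re <- EBImage::imageData(EBImage::filter2(im, k$re, boundary = "replicate"))
    ii <- EBImage::imageData(EBImage::filter2(im, k$im, boundary = "replicate"))
    mag <- sqrt(re^2 + ii^2)
    v <- c(mean(mag), sd(mag))
    names(v) <- sprintf("gabor_f%s_a%d_%s", sub("^0\\.", "", format(f)),
                        a, c("mean", "sd"))
    out <- c(out, v)
  }
  out
}

#' The TCMF feature-name registry
#'
#' Ordered names of the 142 TACS-corresponding microscopic features:
#' 8 morphological, 6 histogram, 80 GLCM and 48 Gabor features. The
#' partition of the 134 textural features among the three families follows
#' the default extraction configuration and is config-driven: passing other
#' displacement/angle/frequency sets changes the registry consistently.
#'
#' @param config a [tacs_config()].
#' @return Character vector of feature names (length 142 under defaults).
#' @export
tcmf_registry <- function(config = tacs_config()) {
  morph <- c("morph_area_fraction", "morph_fiber_count", "morph_mean_length",
             "morph_mean_width", "morph_straightness",
             "morph_crosslink_density", "morph_crosslink_space",
             "morph_orientation_concentration")
  hist <- c("hist_mean", "hist_variance", "hist_skewness", "hist_kurtosis",
            "hist_energy", "hist_entropy")
  glcm <- as.vector(vapply(config$glcm_displacements, function(d)
    vapply(config$glcm_angles, function(a)
      sprintf("glcm_%s_d%d_a%d", c("contrast", "correlation", "energy",
                                   "homogeneity"), d, a),
      character(4)), character(4 * length(config$glcm_angles))))
  gabor <- as.vector(vapply(config$gabor_frequencies, function(f)
    vapply(config$gabor_angles, function(a)
      sprintf("gabor_f%s_a%d_%s", sub("^0\\.", "", format(f)), a,
              c("mean", "sd")),
      character(2)), character(2 * length(config$gabor_angles))))
  c(morph, hist, glcm, gabor)
}

#' Assemble the TCMF vector for one ROI
#'
#' Concatenates morphological and textural features into the ordered,
#' named 142-entry TCMF vector and checks it against the registry.
#'
#' @param morph output of [compute_morph_features()].
#' @param texture named vector combining [histogram_features()],
#'   [glcm_features()] and [gabor_features()] output.
#' @param config a [tacs_config()] (fixes the registry).
#' @return Named numeric vector matching [tcmf_registry()] exactly.
#' @export
assemble_tcmf <- function(morph, texture, config = tacs_config()) {
  v <- c(morph, texture)
  if (!all(is.finite(v)))
    stop("non-finite feature value(s): ",
         paste(head(names(v)[!is.finite(v)], 5), collapse = ", "),
         call. = FALSE)
  reg <- tcmf_registry(config)
  missing_f <- setdiff(reg, names(v))
  if (length(missing_f))
    stop("feature(s) missing from assembly: ",
         paste(head(missing_f, 5), collapse = ", "), call. = FALSE)
  v[reg]
}

#' Extract the full TCMF vector from an SHG image
#'
#' Runs the complete per-ROI pipeline: collagen segmentation, fiber-network
#' tracing, the 8 morphological features, and the 134 textural features
#' (computed on the raw ROI by default; set `texture_masked` in the config
#' to compute them on the collagen-masked image).
#'
#' @param image an [shg_image()].
#' @param config a [tacs_config()].
#' @return Named numeric vector of length 142 in registry order.
#' @examples
#' sim <- simulate_image(image_sim_params(n_px = 64, n_fibers = 4, seed = 1))
#' v <- extract_tcmf(sim$image)
#' length(v)
#' @export
extract_tcmf <- function(image, config = tacs_config()) {
  stopifnot(inherits(image, "shg_image"))
  mask <- segment_collagen(image, method = config$segmentation_method,
                           smooth_sigma_px = config$smooth_sigma_px)
  net <- extract_fiber_network(mask, image$pixel_size_um,
                               min_spur_um = config$min_spur_um,
                               min_fiber_um = config$min_fiber_um,
                               continuation_deg = config$continuation_deg)
  morph <- compute_morph_features(net)
  timg <- image
  if (isTRUE(config$texture_masked)) {
    px <- image$pixels
    px[!mask] <- 0
    timg <- shg_image(px, image$pixel_size_um, image$id, image$bit_depth)
  }
  texture <- c(histogram_features(timg),
               glcm_features(timg, displacements = config$glcm_displacements,
                             angles = config$glcm_angles,
                             levels = config$glcm_levels),
               gabor_features(timg, frequencies = config$gabor_frequencies,
                              angles = config$gabor_angles))
  assemble_tcmf(morph, texture, config)
}
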