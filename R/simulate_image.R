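# Synthetic SHG fiber images with pixel-level ground truth.
#
# Fibers are circular arcs: the curvature parameter is the total turning
# angle phi (radians) of the arc, so ground-truth straightness (endpoint
# chord / arc length) is sin(phi/2)/(phi/2) in closed form. Orientations
# are axial: a von Mises draw on the doubled angle folded to [0, 180).
# Coordinates: math (x, y) with y up; pixel (row, col) has x = col,
# y = (n_row - 1) - row, matching the package orientation convention.

# evaluate code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# von Mises sampler (Best & Fisher rejection); kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1
    }
  }
  out
}

# axial orientation draw on [0, 180) degrees
raxial_deg <- function(n, mean_deg, kappa) {
  th2 <- rvonmises(n, mu = 2 * mean_deg * pi / 180, kappa = kappa)
  (th2 / 2 * 180 / pi) %% 180
}

#' Parameters for the SHG image simulator
#'
#' @param n_px image side in pixels (square image).
#' @param pixel_size_um physical pixel size in micrometres.
#' @param n_fibers number of primary fibers.
#' @param length_um_mean,length_um_sd fiber arc-length distribution (um).
#' @param width_um_mean,width_um_sd fiber stroke-width distribution (um).
#' @param curvature total turning angle phi of each fiber arc in radians
#'   (0 = straight; pi = semicircle). Ground-truth straightness is
#'   `sin(phi/2)/(phi/2)`.
#' @param orientation_mean_deg mean fiber orientation, degrees in [0, 180).
#' @param orientation_kappa concentration of the axial von Mises orientation
#'   distribution (0 = isotropic).
#' @param crosslink_rate expected number of branch fibers spawned per
#'   primary fiber (Poisson).
#' @param intensity peak stroke brightness on the native intensity scale.
#' @param noise_sd additive Gaussian noise sd (native intensity units).
#' @param shot_noise if TRUE, Poisson shot noise is applied before the
#'   Gaussian component.
#' @param bit_depth 8 or 16.
#' @param tacs_archetype optional integer 1..8 recorded for provenance.
#' @param seed random seed; identical parameters and seed give bitwise
#'   identical output.
#' @return A named list of class `image_sim_params`.
#' @export
image_sim_params <- function(n_px = 256, pixel_size_um = 150 / 256,
                             n_fibers = 25,
                             length_um_mean = 40, length_um_sd = 10,
                             width_um_mean = 1.5, width_um_sd = 0.3,
                             curvature = 0.3,
                             orientation_mean_deg = 90,
                             orientation_kappa = 0,
                             crosslink_rate = 0.3,
                             intensity = 180, noise_sd = 8,
                             shot_noise = FALSE, bit_depth = 8,
                             tacs_archetype = NULL, seed = 1) {
  p <- as.list(environment())
  if (p$n_px < 16) stop("image must be at least 16 px per side", call. = FALSE)
  if (p$n_fibers < 0 || p$crosslink_rate < 0 || p$noise_sd < 0 ||
      p$orientation_kappa < 0)
    stop("rates, counts and kappa must be >= 0", call. = FALSE)
  if (p$curvature < 0 || p$curvature >= 2 * pi)
    stop("curvature (turn angle) must be in [0, 2*pi)", call. = FALSE)
  structure(p, class = "image_sim_params")
}

# arc polyline in pixel math coords; phi = turn angle, theta = chord
# orientation (deg), length in px; returned as n x 2 matrix (x, y)
arc_polyline <- function(length_px, phi, theta_deg, step_px = 0.5) {
  n_seg <- max(2L, ceiling(length_px / step_px))
  s <- seq(0, length_px, length.out = n_seg + 1L)
  if (phi < 1e-6) {
    pts <- cbind(s - length_px / 2, 0)
  } else {
    r <- length_px / phi
    t <- s / r - phi / 2            # angle along arc, centred
    # chord endpoints lie on y = r*cos(phi/2); chord is along x
    pts <- cbind(r * sin(t), r * cos(t) - r * cos(phi / 2))
  }
  th <- theta_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts %*% t(rot)
}

# place a centred polyline inside [0, n-1]^2; error if infeasible
place_polyline <- function(pts, n_px) {
  rng_x <- range(pts[, 1]); rng_y <- range(pts[, 2])
  if (diff(rng_x) > n_px - 1 || diff(rng_y) > n_px - 1)
    stop("fiber length infeasible for the image size", call. = FALSE)
  off_x <- runif(1, -rng_x[1], (n_px - 1) - rng_x[2])
  off_y <- runif(1, -rng_y[1], (n_px - 1) - rng_y[2])
  cbind(pts[, 1] + off_x, pts[, 2] + off_y)
}

# accumulate min distance from pixel centres to a polyline into `dmat`
# (n x n, math coords: dmat[row, col], y = n - row); only pixels within
# `reach` px of a segment are updated
polyline_distance <- function(dmat, pts, reach) {
  n <- nrow(dmat)
  for (k in seq_len(nrow(pts) - 1L)) {
    p1 <- pts[k, ]; p2 <- pts[k + 1L, ]
    lo_x <- max(0L, floor(min(p1[1], p2[1]) - reach))
    hi_x <- min(n - 1L, ceiling(max(p1[1], p2[1]) + reach))
    lo_y <- max(0L, floor(min(p1[2], p2[2]) - reach))
    hi_y <- min(n - 1L, ceiling(max(p1[2], p2[2]) + reach))
    if (lo_x > hi_x || lo_y > hi_y) next
    xs <- lo_x:hi_x; ys <- lo_y:hi_y
    px <- rep(xs, times = length(ys))
    py <- rep(ys, each = length(xs))
    d21 <- p2 - p1
    len2 <- sum(d21^2)
    tt <- if (len2 < 1e-12) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - p1[1]) * d21[1] + (py - p1[2]) * d21[2]) / len2))
    dd <- sqrt((px - (p1[1] + tt * d21[1]))^2 + (py - (p1[2] + tt * d21[2]))^2)
    rows <- n - py       # y -> row (1-based): row = n - y
    cols <- px + 1L
    idx <- rows + (cols - 1L) * n
    upd <- dd < dmat[idx]
    dmat[idx[upd]] <- dd[upd]
  }
  dmat
}

#' Simulate an SHG-like collagen fiber image
#'
#' Renders anti-aliased fiber strokes (sum of per-fiber coverage times peak
#' intensity), adds optional shot and Gaussian read noise, clips to the bit
#' depth and returns the image together with the generating fiber
#' specifications and a ground-truth collagen mask (all pixels within half a
#' stroke width of a centerline).
#'
#' @param params an [image_sim_params()] object.
#' @return A list with elements
#'   \describe{
#'     \item{image}{[shg_image()] of the rendered ROI.}
#'     \item{fibers}{list of fiber specs: `id`, `centerline` (n x 2 matrix,
#'       pixel math coords), `width_um`, `intensity`, `orientation_deg`
#'       (chord angle), `length_um`, `straightness`, `parent` (branch
#'       parent id or NA).}
#'     \item{mask}{logical matrix, TRUE on ground-truth fiber pixels.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_image(image_sim_params(n_px = 64, n_fibers = 3, seed = 2))
#' sum(sim$mask)
#' @export
simulate_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  with_seed(params$seed, {
    n <- params$n_px
    psz <- params$pixel_size_um
    maxv <- 2^params$bit_depth - 1
    fibers <- list()
    fid <- 0L
    draw_fiber <- function(theta, start_at = NULL, parent = NA_integer_,
                           len_scale = 1) {
      len_um <- max(2 * psz, rnorm(1, params$length_um_mean * len_scale,
                                   params$length_um_sd * len_scale))
      w_um <- max(0.5 * psz, rnorm(1, params$width_um_mean,
                                   params$width_um_sd))
      len_px <- len_um / psz
      if (len_px > (n - 1) * sqrt(2))
        stop("fiber length infeasible for the image size", call. = FALSE)
      pts <- arc_polyline(min(len_px, n - 1.01), params$curvature, theta)
      pts <- if (is.null(start_at)) place_polyline(pts, n) else {
        # branch: translate so the arc starts at the attachment point,
        # then clamp inside the frame
        shifted <- cbind(pts[, 1] - pts[1, 1] + start_at[1],
                         pts[, 2] - pts[1, 2] + start_at[2])
        keep <- shifted[, 1] >= 0 & shifted[, 1] <= n - 1 &
          shifted[, 2] >= 0 & shifted[, 2] <= n - 1
        if (sum(keep) < 2) return(NULL)
        shifted[keep, , drop = FALSE]
      }
      fid <<- fid + 1L
      seg <- diff(pts)
      arc_len <- sum(sqrt(rowSums(seg^2)))
      chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
      list(id = fid, centerline = pts, width_um = w_um,
           intensity = params$intensity,
           orientation_deg = axial_angle_deg(pts[nrow(pts), 1] - pts[1, 1],
                                             -(pts[nrow(pts), 2] - pts[1, 2])),
           length_um = arc_len * psz,
           straightness = if (arc_len > 0) chord / arc_len else 1,
           parent = parent)
    }
    if (params$n_fibers > 0) {
      thetas <- raxial_deg(params$n_fibers, params$orientation_mean_deg,
                           params$orientation_kappa)
      for (i in seq_len(params$n_fibers)) {
        f <- draw_fiber(thetas[i])
        fibers[[length(fibers) + 1L]] <- f
        # crosslinks: branch new fibers off this one
        n_br <- rpois(1, params$crosslink_rate)
        if (n_br > 0) {
          for (b in seq_len(n_br)) {
            v <- sample(nrow(f$centerline), 1)
            dev <- sample(c(-1, 1), 1) * runif(1, 25, 90)
            fb <- draw_fiber((f$orientation_deg + dev) %% 180,
                             start_at = f$centerline[v, ],
                             parent = f$id, len_scale = 0.6)
            if (!is.null(fb)) fibers[[length(fibers) + 1L]] <- fb
          }
        }
      }
    }
    accum <- matrix(0, n, n)
    mask <- matrix(FALSE, n, n)
    for (f in fibers) {
      w_px <- f$width_um / psz
      dmat <- matrix(Inf, n, n)
      dmat <- polyline_distance(dmat, f$centerline, reach = w_px / 2 + 1.5)
      cover <- pmin(1, pmax(0, w_px / 2 + 0.5 - dmat))
      accum <- accum + f$intensity * cover
      mask <- mask | (dmat <= w_px / 2)
    }
    if (params$shot_noise) {
      accum <- matrix(rpois(n * n, pmax(0, accum)), n, n)
    }
    if (params$noise_sd > 0) {
      accum <- accum + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
    }
    px <- matrix(pmin(maxv, pmax(0, round(accum))), n, n)
    img <- shg_image(px, pixel_size_um = psz,
                     id = sprintf("sim_seed%d", params$seed),
                     bit_depth = params$bit_depth)
    list(image = img, fibers = fibers, mask = mask, params = params)
  })
}

#' TACS archetype presets for the image simulator
#'
#' Parameter presets emulating the eight tumor-associated collagen signature
#' (TACS) patterns at the ROI scale: TACS1 curved fibers wrapping tumor
#' foci (high curvature); TACS2 fibers parallel to the tumor boundary
#' (boundary axis declared at 0 degrees); TACS3 fibers perpendicular to the
#' boundary (radiating pattern); TACS4 reticular crosslinked network; TACS5
#' directionally aligned fibers (high orientation concentration); TACS6
#' chaotic alignment (isotropic); TACS7 dense distribution; TACS8 sparse
#' distribution.
#'
#' @param pattern_id integer 1..8.
#' @param seed random seed.
#' @param ... overrides forwarded to [image_sim_params()].
#' @return As [simulate_image()]; the result additionally carries
#'   `boundary_axis_deg` (0) for patterns 2 and 3.
#' @export
simulate_tacs_archetype <- function(pattern_id, seed = 1, ...) {
  if (!length(pattern_id) == 1 || !pattern_id %in% 1:8)
    stop("`pattern_id` must be an integer in 1..8", call. = FALSE)
  presets <- list(
    `1` = list(curvature = 2.8, orientation_kappa = 0, n_fibers = 25),
    `2` = list(curvature = 0.3, orientation_mean_deg = 0,
               orientation_kappa = 8, n_fibers = 25),
    `3` = list(curvature = 0.3, orientation_mean_deg = 90,
               orientation_kappa = 8, n_fibers = 25),
    `4` = list(curvature = 0.5, orientation_kappa = 0, crosslink_rate = 3,
               n_fibers = 18),
    `5` = list(curvature = 0.2, orientation_mean_deg = 45,
               orientation_kappa = 12, n_fibers = 25),
    `6` = list(curvature = 0.8, orientation_kappa = 0, n_fibers = 25),
    `7` = list(curvature = 0.4, orientation_kappa = 0, n_fibers = 60),
    `8` = list(curvature = 0.4, orientation_kappa = 0, n_fibers = 7)
  )[[as.character(pattern_id)]]
  args <- modifyList(c(presets, list(seed = seed,
                                     tacs_archetype = as.integer(pattern_id))),
                     list(...))
  out <- simulate_image(do.call(image_sim_params, args))
  if (pattern_id %in% 2:3) out$boundary_axis_deg <- 0
  out
}
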