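# Independent oracle implementations and fixture builders. These stay
# deliberately naive (double loops, grid searches) so they cannot share a
# bug with the package code paths they check.

# --- mask fixtures ---------------------------------------------------------

line_mask <- function(n = 120, row = 60, from = 10, to = 110) {
  m <- matrix(FALSE, n, n)
  m[row, from:to] <- TRUE
  m
}

plus_mask <- function(n = 41) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1) / 2
  m[c0, 5:(n - 4)] <- TRUE
  m[5:(n - 4), c0] <- TRUE
  m
}

semicircle_mask <- function(n = 120, r = 40) {
  th <- seq(0, pi, length.out = 6 * r)
  m <- matrix(FALSE, n, n)
  m[cbind(round(n / 2 + r * sin(th)), round(n / 2 + r * cos(th)))] <- TRUE
  m
}

# a fabricated network of straight 2-point fibers at given angles (degrees)
angles_network <- function(angles_deg, pixel_size_um = 1) {
  fibers <- lapply(angles_deg, function(a) {
    # (row, col) polyline: row decreases with sin for CCW-from-+x angles
    rbind(c(50, 50), c(50 - 20 * sin(a * pi / 180), 50 + 20 * cos(a * pi / 180)))
  })
  structure(list(fibers = fibers, crosslinks = matrix(numeric(0), 0, 2),
                 link_spans_um = numeric(0),
                 skeleton = matrix(FALSE, 100, 100),
                 mask = matrix(FALSE, 100, 100),
                 pixel_size_um = pixel_size_um),
            class = "fiber_network")
}

# --- GLCM brute force ------------------------------------------------------

# independent quantizer matching the documented min-max rule
oracle_quantize <- function(px, levels) {
  rng <- range(px)
  if (diff(rng) == 0) return(matrix(1L, nrow(px), ncol(px)))
  q <- 1L + floor((px - rng[1]) / diff(rng) * levels)
  q[q > levels] <- levels
  matrix(as.integer(q), nrow(px), ncol(px))
}

# exhaustive symmetric pair enumeration; angle CCW from +x, screen rows down
oracle_glcm <- function(q, levels, d, angle) {
  off <- switch(as.character(angle), "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  P / sum(P)
}

oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  con <- 0; ene <- 0; hom <- 0
  for (i in 1:L) for (j in 1:L) {
    con <- con + (i - j)^2 * P[i, j]
    ene <- ene + P[i, j]^2
    hom <- hom + P[i, j] / (1 + (i - j)^2)
  }
  mu <- sum((1:L) * rowSums(P))
  s2 <- sum(((1:L) - mu)^2 * rowSums(P))
  cor_ <- 0
  if (s2 > 0)
    for (i in 1:L) for (j in 1:L)
      cor_ <- cor_ + (i - mu) * (j - mu) * P[i, j] / s2
  c(contrast = con, correlation = cor_, energy = ene, homogeneity = hom)
}

# --- survival oracles ------------------------------------------------------

# exhaustive Harrell C: usable pairs (i, j) with t_i < t_j and event_i = 1
oracle_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# grid-search maximum of the (untied) Cox partial likelihood, one covariate
oracle_cox_beta <- function(x, time, event, grid = seq(-3, 3, by = 1e-3)) {
  ll <- vapply(grid, function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# naive IPCW cumulative/dynamic AUC: explicit double loop over all
# case/control pairs with KM censoring weights
oracle_ipcw_auc <- function(scores, time, event, horizon) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t, minus = FALSE) {
    keep <- if (minus) cens_fit$time < t else cens_fit$time <= t
    if (!any(keep)) 1 else max(min(cens_fit$surv[keep]), 1e-10)
  }
  ci <- which(event == 1 & time <= horizon)
  cj <- which(time > horizon)
  num <- 0; den <- 0
  for (i in ci) for (j in cj) {
    w <- (1 / G(time[i], minus = TRUE)) * (1 / G(horizon))
    den <- den + w
    if (scores[i] > scores[j]) num <- num + w
    else if (scores[i] == scores[j]) num <- num + w / 2
  }
  num / den
}

# --- small helpers ---------------------------------------------------------

quick_sim <- function(seed = 1, n_px = 96, ...) {
  simulate_image(image_sim_params(n_px = n_px, pixel_size_um = 150 / 256,
                                  seed = seed, ...))
}

# fast config for small test images
test_config <- function(...) tacs_config(pixel_size_um = 150 / 256, ...)
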