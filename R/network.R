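# Fiber-network tracing: binary skeletonization (Zhang-Suen), spur pruning,
# crosslink (branch-point) detection and fiber path assembly with a smooth
# continuation rule at junctions.

# Zhang-Suen thinning of a logical matrix; returns an 8-connected skeleton
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# adjacency list of skeleton pixels (8-connectivity, minimal form: a
# diagonal edge is kept only when neither flanking orthogonal pixel is on
# the skeleton, so staircase corners do not inflate the degree)
# coords: k x 2 matrix (row, col); returns list of integer neighbour ids
skeleton_adjacency <- function(coords, nr, nc) {
  k <- nrow(coords)
  id_map <- matrix(0L, nr, nc)
  id_map[coords] <- seq_len(k)
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- integer(length(rr))
    out[ok] <- id_map[cbind(rr[ok], cc[ok])]
    out
  }
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  adj <- vector("list", k)
  for (i in seq_len(k)) adj[[i]] <- integer(0)
  for (o in seq_len(8)) {
    dr <- offs[o, 1]; dc <- offs[o, 2]
    nbr <- at(coords[, 1] + dr, coords[, 2] + dc)
    if (dr != 0 && dc != 0) {
      # drop diagonal edge if an orthogonal flanker connects the two
      flank <- at(coords[, 1] + dr, coords[, 2]) > 0L |
        at(coords[, 1], coords[, 2] + dc) > 0L
      nbr[flank] <- 0L
    }
    hit <- which(nbr > 0L)
    for (i in hit) adj[[i]] <- c(adj[[i]], nbr[i])
  }
  adj
}

# walk from pixel `from` (not a junction) away from `prev` until hitting a
# junction, an endpoint, or a visited pixel; returns the path of pixel ids
walk_path <- function(adj, deg, from, prev) {
  path <- from
  cur <- from
  repeat {
    nxt <- setdiff(adj[[cur]], prev)
    # avoid doubling back through diagonal+orthogonal redundancy: drop
    # neighbours of the previous pixel already adjacent to it
    if (length(nxt) > 1 && length(prev))
      nxt <- setdiff(nxt, adj[[prev[1]]])
    if (!length(nxt)) break
    nxt <- nxt[1]
    if (nxt %in% path) break           # closed loop guard
    path <- c(path, nxt)
    if (deg[nxt] != 2) break
    prev <- cur
    cur <- nxt
  }
  path
}

#' Trace the collagen fiber network from a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), prunes spurs shorter than
#' `min_spur_um`, merges adjacent skeleton branch points (degree >= 3) into
#' crosslinks (connected-component centroids), extracts the skeleton
#' segments between endpoints/crosslinks and joins segments across a
#' crosslink when their incoming tangents differ by less than
#' `continuation_deg` (smooth continuation). Fibers shorter than
#' `min_fiber_um` are discarded.
#'
#' @param mask logical collagen mask.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param min_spur_um minimum spur length retained (default 3 um).
#' @param min_fiber_um minimum fiber length retained (default 5 um).
#' @param continuation_deg maximum tangent difference (degrees) for joining
#'   fibers across a crosslink (default 20).
#' @return An object of class `fiber_network`: list with `fibers` (list of
#'   polylines, n x 2 matrices of (row, col) pixel coordinates, subpixel at
#'   joined crosslinks), `crosslinks` (m x 2 matrix of branch-point
#'   centroids), `link_spans_um` (skeleton path lengths between adjacent
#'   crosslinks), `skeleton` (logical matrix), `mask`, `pixel_size_um`.
#'   An empty mask gives an empty network.
#' @export
extract_fiber_network <- function(mask, pixel_size_um,
                                  min_spur_um = 3, min_fiber_um = 5,
                                  continuation_deg = 20) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0)
  nr <- nrow(mask); nc <- ncol(mask)
  empty <- function(skel) structure(
    list(fibers = list(), crosslinks = matrix(numeric(0), 0, 2),
         link_spans_um = numeric(0), skeleton = skel, mask = mask,
         pixel_size_um = pixel_size_um),
    class = "fiber_network")
  if (!any(mask)) return(empty(mask))
  skel <- skeletonize(mask)
  min_spur_px <- min_spur_um / pixel_size_um

  # iterative spur pruning on the skeleton pixel graph
  repeat {
    coords <- which(skel, arr.ind = TRUE)
    if (nrow(coords) == 0) return(empty(skel))
    adj <- skeleton_adjacency(coords, nr, nc)
    deg <- lengths(adj)
    ends <- which(deg == 1)
    removed_any <- FALSE
    alive <- rep(TRUE, nrow(coords))
    for (e in ends) {
      if (!alive[e]) next
      path <- walk_path(adj, deg, e, integer(0))
      last <- path[length(path)]
      if (deg[last] >= 3 && length(path) >= 2) {
        body <- path[-length(path)]
        steps <- sqrt(rowSums((coords[body, , drop = FALSE] -
                                 coords[path[-1], , drop = FALSE])^2))
        if (sum(steps) < min_spur_px) {
          skel[coords[body, , drop = FALSE]] <- FALSE
          alive[body] <- FALSE
          removed_any <- TRUE
        }
      }
    }
    if (!removed_any) break
  }

  coords <- which(skel, arr.ind = TRUE)
  if (nrow(coords) == 0) return(empty(skel))
  adj <- skeleton_adjacency(coords, nr, nc)
  deg <- lengths(adj)
  is_junc <- deg >= 3

  # merge adjacent junction pixels into crosslink components
  junc_ids <- which(is_junc)
  junc_comp <- integer(length(deg))      # 0 = not a junction
  crosslinks <- matrix(numeric(0), 0, 2)
  if (length(junc_ids)) {
    el <- do.call(rbind, lapply(junc_ids, function(i) {
      nb <- intersect(adj[[i]], junc_ids)
      if (length(nb)) cbind(i, nb) else NULL
    }))
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(if (is.null(el)) integer(0) else el[, 1]),
                 to = as.character(if (is.null(el)) integer(0) else el[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(junc_ids)))
    comp <- igraph::components(g)$membership
    junc_comp[as.integer(names(comp))] <- as.integer(comp)
    crosslinks <- do.call(rbind, lapply(seq_len(max(comp)), function(ci) {
      colMeans(coords[as.integer(names(comp))[comp == ci], , drop = FALSE])
    }))
  }

  # segments: maximal paths of non-junction pixels; each records the
  # crosslink component (if any) touching each end
  seg_list <- list()
  visited <- is_junc                      # junction pixels excluded
  non_junc <- which(!is_junc)
  adj_nj <- lapply(seq_along(adj), function(i) {
    if (is_junc[i]) integer(0) else setdiff(adj[[i]], which(is_junc))
  })
  deg_nj <- lengths(adj_nj)
  # start walks at path endpoints first, then sweep leftovers (loops)
  starts <- c(non_junc[deg_nj[non_junc] <= 1],
              non_junc[deg_nj[non_junc] > 1])
  for (s in starts) {
    if (visited[s]) next
    path <- walk_path(adj_nj, deg_nj, s, integer(0))
    # extend walk across visited==FALSE only; mark and walk other direction
    if (length(path) > 1 && deg_nj[s] > 1) {
      back <- walk_path(adj_nj, deg_nj, s, path[2])
      path <- c(rev(back[-1]), path)
    }
    if (any(visited[path])) path <- path[!visited[path] | path == path[1]]
    visited[path] <- TRUE
    ends_ <- c(path[1], path[length(path)])
    touch <- vapply(ends_, function(p) {
      jn <- junc_comp[adj[[p]]]
      jn <- jn[jn > 0]
      if (length(jn)) jn[1] else 0L
    }, integer(1))
    seg_list[[length(seg_list) + 1L]] <-
      list(pixels = path, cross_a = touch[1], cross_b = touch[2])
  }

  # tangent of a segment entering end `which_end` (direction of travel into
  # the adjoining junction), from up to 5 terminal pixels
  seg_tangent <- function(seg, which_end) {
    px <- coords[seg$pixels, , drop = FALSE]
    if (which_end == 1) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
    k <- min(5, nrow(px))
    tailpx <- px[(nrow(px) - k + 1):nrow(px), , drop = FALSE]
    d <- tailpx[k, ] - tailpx[1, ]
    if (all(d == 0)) c(0, 0) else d / sqrt(sum(d^2))
  }

  # pair segments across each crosslink by smooth continuation
  n_seg <- length(seg_list)
  pairings <- list()
  if (n_seg && nrow(crosslinks)) {
    for (ci in seq_len(nrow(crosslinks))) {
      inc <- list()   # (segment id, end id, direction into junction)
      for (si in seq_len(n_seg)) {
        if (seg_list[[si]]$cross_a == ci)
          inc[[length(inc) + 1L]] <- list(si = si, end = 1L,
                                          dir = seg_tangent(seg_list[[si]], 1L))
        if (seg_list[[si]]$cross_b == ci)
          inc[[length(inc) + 1L]] <- list(si = si, end = 2L,
                                          dir = seg_tangent(seg_list[[si]], 2L))
      }
      if (length(inc) < 2) next
      cand <- NULL
      for (i in seq_len(length(inc) - 1)) for (j in (i + 1):length(inc)) {
        # continuation: travel directions into the junction are opposed
        cosang <- -sum(inc[[i]]$dir * inc[[j]]$dir)
        dev <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        cand <- rbind(cand, c(i, j, dev))
      }
      cand <- cand[cand[, 3] < continuation_deg, , drop = FALSE]
      if (!nrow(cand)) next
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      used <- logical(length(inc))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        pairings[[length(pairings) + 1L]] <-
          list(a = c(inc[[i]]$si, inc[[i]]$end),
               b = c(inc[[j]]$si, inc[[j]]$end), cross = ci)
      }
    }
  }

  # chain segments through pairings into fibers
  # build a graph over segment-end nodes: node id = 2*(si-1) + end
  node <- function(si, end) 2L * (si - 1L) + end
  edges <- c()
  for (si in seq_len(n_seg)) edges <- c(edges, node(si, 1L), node(si, 2L))
  pair_cross <- list()
  for (p in pairings) {
    edges <- c(edges, node(p$a[1], p$a[2]), node(p$b[1], p$b[2]))
    pair_cross[[paste(sort(c(node(p$a[1], p$a[2]), node(p$b[1], p$b[2]))),
                      collapse = "_")]] <- p$cross
  }
  fibers <- list()
  if (n_seg) {
    g <- igraph::make_graph(edges = as.character(edges), directed = FALSE)
    comp <- igraph::components(g)
    for (ci in seq_len(comp$no)) {
      nodes <- as.integer(igraph::V(g)$name[comp$membership == ci])
      degs <- igraph::degree(g)[comp$membership == ci]
      start <- if (any(degs == 1)) nodes[which(degs == 1)[1]] else nodes[1]
      # walk the chain alternating intra-segment and pairing edges
      poly <- NULL
      cur <- start
      prev <- -1L
      repeat {
        si <- (cur - 1L) %/% 2L + 1L
        end <- (cur - 1L) %% 2L + 1L
        other <- node(si, 3L - end)
        px <- coords[seg_list[[si]]$pixels, , drop = FALSE]
        if (end == 2L) px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
        poly <- rbind(poly, px)
        # move across a pairing from `other`, if present and not whence we came
        nbrs <- as.integer(igraph::V(g)$name[
          as.integer(igraph::neighbors(g, as.character(other)))])
        nbrs <- setdiff(nbrs, c(cur, prev))
        if (!length(nbrs)) break
        nxt <- nbrs[1]
        key <- paste(sort(c(other, nxt)), collapse = "_")
        if (!is.null(pair_cross[[key]]))
          poly <- rbind(poly, crosslinks[pair_cross[[key]], , drop = FALSE])
        prev <- other
        cur <- nxt
        if (cur == start) break   # closed loop
      }
      if (!is.null(poly) && nrow(poly) >= 2) {
        fibers[[length(fibers) + 1L]] <- unname(poly)
      }
    }
  }

  # smooth polylines (moving average, endpoints kept) so arc lengths are
  # not inflated by staircase digitization
  smooth_polyline <- function(p, k = 5L) {
    n_p <- nrow(p)
    if (n_p <= 2) return(p)
    half <- k %/% 2L
    sm <- p
    for (i in seq_len(n_p)) {
      w <- max(1L, i - half):min(n_p, i + half)
      sm[i, ] <- colMeans(p[w, , drop = FALSE])
    }
    sm[1, ] <- p[1, ]; sm[n_p, ] <- p[n_p, ]
    sm
  }
  fibers <- lapply(fibers, smooth_polyline)

  # drop short fibers
  polyline_length_px <- function(p)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  keep <- vapply(fibers, function(p)
    polyline_length_px(p) * pixel_size_um >= min_fiber_um, logical(1))
  fibers <- fibers[keep]

  # skeleton path lengths between adjacent (distinct) crosslinks
  spans <- vapply(seg_list, function(s) {
    if (s$cross_a > 0 && s$cross_b > 0 && s$cross_a != s$cross_b) {
      px <- coords[s$pixels, , drop = FALSE]
      polyline_length_px(px) * pixel_size_um
    } else NA_real_
  }, numeric(1))
  spans <- spans[!is.na(spans)]

  structure(
    list(fibers = fibers, crosslinks = crosslinks,
         link_spans_um = spans, skeleton = skel, mask = mask,
         pixel_size_um = pixel_size_um),
    class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf("<fiber_network> %d fiber(s), %d crosslink(s), %d skeleton px\n",
              length(x$fibers), nrow(x$crosslinks), sum(x$skeleton)))
  invisible(x)
}
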