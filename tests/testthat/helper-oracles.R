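# Independent oracles, deliberately naive: these re-derive expected results
# by brute force and must stay independent of the package implementation.

# 8-connectivity labelling by iterative label propagation: every true cell
# starts with a unique id and repeatedly takes the minimum id among its
# 8-neighbours until a fixed point; components then get compact ids in
# row-major first-encounter order.
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  pad <- function(m) rbind(Inf, cbind(Inf, m, Inf), Inf)
  repeat {
    p <- pad(ifelse(lab == 0, Inf, lab))
    nb <- pmin(p[1:nr, 1:nc], p[1:nr, 2:(nc + 1)], p[1:nr, 3:(nc + 2)],
               p[2:(nr + 1), 1:nc], p[2:(nr + 1), 3:(nc + 2)],
               p[3:(nr + 2), 1:nc], p[3:(nr + 2), 2:(nc + 1)],
               p[3:(nr + 2), 3:(nc + 2)])
    new <- ifelse(mask, pmin(ifelse(lab == 0, Inf, lab), nb), 0)
    new[!is.finite(new)] <- 0
    if (all(new == lab)) break
    lab <- new
  }
  # compact ids in row-major first-encounter order
  tl <- t(lab); ids <- tl[tl > 0]
  first <- ids[!duplicated(ids)]
  map <- integer(max(c(first, 1))); map[first] <- seq_along(first)
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

# exhaustive nearest-point assignment (ties -> lower index)
oracle_nearest <- function(pts, centres) {
  apply(centres, 1, function(p) {
    d <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
    which.min(d)   # which.min returns the first (lowest index) minimum
  })
}

# gift-wrapping (Jarvis march) convex hull, counter-clockwise
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == n) start else setdiff(seq_len(n), cur)[1]
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_cand <- sum((pts[cand, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr > 1e-12 || (abs(cr) <= 1e-12 && d_j > d_cand)) cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# hulls as canonical vertex sets for order-independent comparison
hull_vertex_set <- function(h) {
  h <- round(h, 9)
  h[order(h[, 1], h[, 2]), , drop = FALSE]
}

make_uniform_raster <- function(nr, nc, value, cell_size = 100) {
  suit_raster(matrix(value, nr, nc), cell_size, 0, 0)
}
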