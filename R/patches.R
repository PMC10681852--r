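#' Home-range size-class bounds
#'
#' Bounds (km^2) used to classify habitat patches relative to the species'
#' home-range area: patches below `small_max` cannot hold a home range,
#' patches above `large_min` exceed the typical home range and are split by
#' the Vor-Con method. Defaults correspond to a home-range interval of
#' 0.06-1.5 km^2 with an average of about 1 km^2.
#'
#' @param small_max Upper bound of the "small" class (default 0.06 km^2).
#' @param large_min Lower bound of the "large" class (default 1 km^2).
#' @param home_range_upper Upper limit of the home-range area (1.5 km^2).
#' @return A list of class `size_class_bounds`.
#' @export
size_class_bounds <- function(small_max = 0.06, large_min = 1.0,
                              home_range_upper = 1.5) {
  stopifnot(small_max > 0, small_max < large_min,
            large_min <= home_range_upper)
  structure(list(small_max = small_max, large_min = large_min,
                 home_range_upper = home_range_upper),
            class = "size_class_bounds")
}

#' Classify a patch area into a home-range size class
#'
#' `small` if area < `small_max`; `medium` if `small_max` <= area <=
#' `large_min` (closed upper bound); `large` if area > `large_min`.
#'
#' @param area Patch area(s) in km^2 (>= 0).
#' @param bounds A [size_class_bounds].
#' @return Character vector in `c("small", "medium", "large")`.
#' @export
classify_patch_size <- function(area, bounds = size_class_bounds()) {
  if (any(area < 0)) stop("patch area must be non-negative", call. = FALSE)
  ifelse(area < bounds$small_max, "small",
         ifelse(area <= bounds$large_min, "medium", "large"))
}

#' Binary suitability mask
#'
#' A cell is suitable iff its value is at or above the threshold (the
#' threshold is inclusive) and the cell is not nodata.
#'
#' @param hsm A [suit_raster].
#' @param theta Suitability threshold in (0, 1).
#' @return Logical matrix (no `NA`s; nodata cells are `FALSE`).
#' @export
threshold_mask <- function(hsm, theta) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)", call. = FALSE)
  m <- !is.na(hsm$values) & hsm$values >= theta
  m
}

#' Label 8-connected components of a binary mask
#'
#' Cells that touch in any of the eight directions (including diagonals)
#' share a label. Labels are assigned in row-major first-encounter order
#' (left to right within the top row first), so the result is deterministic.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_contiguous <- function(mask) {
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  .cc_label_cpp(mask)
}

#' Remove labelled components below a minimum area
#'
#' Components with `n_cells * cell_area < min_area` (strictly smaller) are
#' relabelled to background; survivors are re-indexed 1..k in row-major
#' first-encounter order.
#'
#' @param labels Integer label matrix (0 = background).
#' @param min_area Minimum area in km^2 (inclusive: exactly `min_area` is kept).
#' @param cell_area Area of one cell in km^2.
#' @return Re-indexed integer label matrix.
#' @export
filter_by_area <- function(labels, min_area, cell_area) {
  if (min_area <= 0) return(labels)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes * cell_area >= min_area - 1e-12)
  out <- labels
  out[!(labels %in% keep)] <- 0L
  relabel_first_encounter(out)
}

# re-index positive labels to 1..k in row-major first-encounter order
relabel_first_encounter <- function(labels) {
  tl <- t(labels)                       # row-major scan of original matrix
  ids <- tl[tl > 0]
  if (!length(ids)) return(labels)
  first <- ids[!duplicated(ids)]
  map <- integer(max(first))
  map[first] <- seq_along(first)
  out <- labels
  pos <- labels > 0
  out[pos] <- map[labels[pos]]
  out
}

#' Spatially balanced, suitability-weighted point sample
#'
#' Draws points whose locations are biased towards more suitable cells
#' (inclusion probability proportional to the cell's weight), subject to a
#' minimum pairwise distance. Cells are ranked with exponential
#' weighted-sampling keys, then accepted greedily in rank order; each
#' accepted cell contributes its centre plus a uniform jitter within the
#' cell. If the distance constraint makes the target unreachable within
#' 50x oversampling, fewer points are returned with a warning.
#'
#' @param weight_raster A [suit_raster] supplying the sampling weights.
#' @param mask Logical matrix of cells eligible for sampling.
#' @param density Target density in points per km^2 (ignored if `n` given).
#' @param min_distance Minimum distance between points, metres (0 disables).
#' @param seed Optional integer seed (`set.seed` is called when non-NULL).
#' @param n Optional explicit number of points, overriding `density`.
#' @return List of class `balanced_points`: `points` (n x 2 matrix),
#'   `cells` (matrix cell index of each point), plus the call parameters.
#' @export
sample_balanced_points <- function(weight_raster, mask, density = 1,
                                   min_distance = 150, seed = NULL, n = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- weight_raster$cell_size
  cell_area_km2 <- (cs / 1000)^2
  idx <- which(mask & !is.na(weight_raster$values))
  if (!length(idx)) stop("sampling mask is empty", call. = FALSE)
  w <- weight_raster$values[idx]
  idx <- idx[w > 0]; w <- w[w > 0]
  if (!length(idx)) stop("all sampling weights are zero", call. = FALSE)
  if (is.null(n)) {
    if (density <= 0) stop("density must be > 0", call. = FALSE)
    n <- max(1L, as.integer(round_half_up(density * length(idx) * cell_area_km2)))
  }
  n <- min(n, length(idx))
  # Efraimidis-Spirakis keys: sorting by -log(u)/w ascending gives a
  # weighted sample without replacement in draw order.
  keys <- -log(stats::runif(length(idx))) / w
  ord <- order(keys)
  centres <- cell_centres(weight_raster)
  nr <- nrow(weight_raster$values)
  accepted <- matrix(numeric(0), ncol = 2)
  acc_cells <- integer(0)
  # spatial hash on a min_distance grid for the pairwise-distance check
  hash <- new.env(parent = emptyenv())
  max_attempts <- 50L * n
  attempts <- 0L
  for (k in ord) {
    if (nrow(accepted) >= n || attempts >= max_attempts) break
    attempts <- attempts + 1L
    cell <- idx[k]
    pt <- centres[cell, ] + (stats::runif(2) - 0.5) * cs
    if (min_distance > 0) {
      hx <- floor(pt[1] / min_distance); hy <- floor(pt[2] / min_distance)
      clash <- FALSE
      for (dx in -1:1) for (dy in -1:1) {
        key <- paste(hx + dx, hy + dy)
        pts <- hash[[key]]
        if (!is.null(pts) &&
            any((pts[, 1] - pt[1])^2 + (pts[, 2] - pt[2])^2 < min_distance^2)) {
          clash <- TRUE
        }
      }
      if (clash) next
      key <- paste(hx, hy)
      hash[[key]] <- rbind(hash[[key]], pt)
    }
    accepted <- rbind(accepted, pt)
    acc_cells <- c(acc_cells, cell)
  }
  if (nrow(accepted) < n)
    warning(sprintf("placed %d of %d requested points (min-distance constraint)",
                    nrow(accepted), n), call. = FALSE)
  dimnames(accepted) <- list(NULL, c("x", "y"))
  structure(list(points = accepted, cells = acc_cells,
                 density = density, min_distance = min_distance, seed = seed),
            class = "balanced_points")
}

#' Assign masked cells to their nearest generating point
#'
#' Rasterised Thiessen/Voronoi tessellation: every masked cell takes the id
#' of the generating point nearest to its centre (Euclidean distance). Ties
#' go to the lower point index.
#'
#' @param points A `balanced_points` object or an n x 2 coordinate matrix.
#' @param mask Logical matrix of cells to assign.
#' @param raster A [suit_raster] supplying the grid geometry.
#' @return Integer label matrix (0 outside the mask), labels = point index.
#' @export
voronoi_assign <- function(points, mask, raster) {
  pts <- if (inherits(points, "balanced_points")) points$points else points
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (!nrow(pts)) stop("at least one generating point required", call. = FALSE)
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(out)
  centres <- cell_centres(raster)[idx, , drop = FALSE]
  best_d <- rep(Inf, length(idx))
  best_i <- integer(length(idx))
  for (i in seq_len(nrow(pts))) {
    d <- (centres[, 1] - pts[i, 1])^2 + (centres[, 2] - pts[i, 2])^2
    upd <- d < best_d            # strict: ties keep the lower index
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  out[idx] <- best_i
  out
}

# Build a patch_landscape from a label matrix; per-patch mean suitability is
# always computed from the continuous HSM.
build_patch_landscape <- function(labels, hsm, method,
                                  bounds = size_class_bounds()) {
  labels <- relabel_first_encounter(labels)
  cs <- hsm$cell_size
  cell_area <- (cs / 1000)^2
  pos <- which(labels > 0)
  if (length(pos)) {
    ids <- labels[pos]
    n_cells <- tabulate(ids)
    sums <- as.numeric(rowsum(hsm$values[pos], ids))
    tab <- data.frame(id = seq_along(n_cells),
                      n_cells = n_cells,
                      area_km2 = n_cells * cell_area,
                      mean_suit = sums / n_cells,
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(id = integer(0), n_cells = integer(0),
                      area_km2 = numeric(0), mean_suit = numeric(0))
  }
  tab$size_class <- if (nrow(tab)) classify_patch_size(tab$area_km2, bounds) else character(0)
  tab$method <- rep(method, nrow(tab))
  pr <- labels
  pr[is.na(hsm$values)] <- NA_integer_
  structure(list(patch_raster = pr, table = tab, cell_size = cs,
                 xll = hsm$xll, yll = hsm$yll, method = method),
            class = "patch_landscape")
}

#' @export
print.patch_landscape <- function(x, ...) {
  cat(sprintf("<patch_landscape> method=%s, %d patches, total %.2f km2\n",
              x$method, nrow(x$table), sum(x$table$area_km2)))
  invisible(x)
}

#' Grid delineation: resample the suitability surface into square blocks
#'
#' Aggregates the raster into square blocks (default 1 km) anchored at the
#' raster origin, computes the mean suitability of the member cells, and
#' drops blocks whose mean falls strictly below the threshold. Each
#' surviving block becomes one patch.
#'
#' @param hsm A [suit_raster].
#' @param theta Suitability threshold.
#' @param grid_cell_m Block edge in metres; must be a multiple of the raster
#'   cell size (default 1000).
#' @return A `patch_landscape`.
#' @export
delineate_grid <- function(hsm, theta, grid_cell_m = 1000) {
  cs <- hsm$cell_size
  b <- grid_cell_m / cs
  if (abs(b - round(b)) > 1e-9)
    stop("grid_cell_m must be a multiple of the raster cell size", call. = FALSE)
  b <- as.integer(round(b))
  v <- hsm$values
  nr <- nrow(v); nc <- ncol(v)
  # blocks anchored at the lower-left raster origin
  iy <- (nr - seq_len(nr)) %/% b          # per matrix row
  ix <- (seq_len(nc) - 1L) %/% b          # per matrix col
  block <- outer(iy, ix, function(a, b2) a * (max(ix) + 1L) + b2 + 1L)
  ok <- !is.na(v)
  means <- tapply(v[ok], block[ok], mean)
  keep <- as.integer(names(means)[means >= theta])
  labels <- matrix(0L, nr, nc)
  sel <- ok & (block %in% keep)
  labels[sel] <- block[sel]
  build_patch_landscape(labels, hsm, "grid")
}

#' Contiguity delineation: threshold, 8-connect, and filter by area
#'
#' Cells below the threshold are removed, 8-connected suitable cells are
#' merged into patches, and patches smaller than the lower home-range limit
#' are dropped. No upper size limit is applied, so very large contiguous
#' patches survive (the configuration the Vor-Con method corrects).
#'
#' @param hsm A [suit_raster].
#' @param theta Suitability threshold.
#' @param bounds A [size_class_bounds]; `small_max` is the area filter.
#' @return A `patch_landscape`.
#' @export
delineate_contiguity <- function(hsm, theta, bounds = size_class_bounds()) {
  mask <- threshold_mask(hsm, theta)
  labels <- label_contiguous(mask)
  cell_area <- (hsm$cell_size / 1000)^2
  labels <- filter_by_area(labels, bounds$small_max, cell_area)
  build_patch_landscape(labels, hsm, "contiguity", bounds)
}

#' Voronoi delineation: suitability-weighted tessellation of the extent
#'
#' Points are sampled over the whole (non-nodata) extent at the target
#' density, weighted by suitability; Voronoi cells are rasterised; patches
#' whose mean continuous suitability falls below the threshold are removed.
#'
#' @param hsm A [suit_raster].
#' @param theta Suitability threshold.
#' @param density Points per km^2 (default 1).
#' @param min_distance Minimum point spacing in metres (default 150).
#' @param seed Integer seed for the point sample.
#' @return A `patch_landscape`.
#' @export
delineate_voronoi <- function(hsm, theta, density = 1, min_distance = 150,
                              seed = NULL) {
  full <- !is.na(hsm$values)
  pts <- sample_balanced_points(hsm, full, density, min_distance, seed)
  labels <- voronoi_assign(pts, full, hsm)
  pl <- build_patch_landscape(labels, hsm, "voronoi")
  keep <- pl$table$id[pl$table$mean_suit >= theta]
  lab2 <- pl$patch_raster
  lab2[!(lab2 %in% keep)] <- 0L
  lab2[is.na(lab2)] <- 0L
  build_patch_landscape(lab2, hsm, "voronoi")
}

#' Vor-Con delineation: contiguity patches with large patches split
#'
#' Contiguity patches are classified by home-range size: small patches are
#' dropped, medium patches pass through unchanged, and each large patch is
#' partitioned by a Voronoi tessellation of suitability-weighted points
#' sampled within that patch only (about one point per km^2 of patch area,
#' minimum two), so no sub-patch spans two parents and the union of
#' sub-patches equals the parent exactly.
#'
#' @inheritParams delineate_contiguity
#' @param density Point density within large patches (points per km^2).
#' @param min_distance Minimum point spacing in metres.
#' @param seed Integer seed.
#' @return A `patch_landscape`.
#' @export
delineate_vorcon <- function(hsm, theta, bounds = size_class_bounds(),
                             density = 1, min_distance = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- delineate_contiguity(hsm, theta, bounds)
  labels <- base$patch_raster
  labels[is.na(labels)] <- 0L
  tab <- base$table
  out <- matrix(0L, nrow(labels), ncol(labels))
  next_id <- 0L
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    cells <- labels == id
    if (tab$size_class[i] == "medium") {
      next_id <- next_id + 1L
      out[cells] <- next_id
    } else if (tab$size_class[i] == "large") {
      n_pts <- max(2L, as.integer(round_half_up(density * tab$area_km2[i])))
      pts <- sample_balanced_points(hsm, cells, min_distance = min_distance,
                                    n = n_pts)
      sub <- voronoi_assign(pts, cells, hsm)
      used <- sort(unique(sub[sub > 0]))
      map <- integer(max(used)); map[used] <- next_id + seq_along(used)
      pos <- sub > 0
      out[pos] <- map[sub[pos]]
      next_id <- next_id + length(used)
    }
    # small patches: dropped
  }
  build_patch_landscape(out, hsm, "vorcon", bounds)
}

#' Delineate patches with any of the four methods
#'
#' @param hsm A [suit_raster].
#' @param method One of `"grid"`, `"voronoi"`, `"contiguity"`, `"vorcon"`.
#' @param theta Suitability threshold (default 0.56).
#' @param ... Passed to the method-specific function.
#' @return A `patch_landscape`.
#' @export
delineate <- function(hsm, method = c("vorcon", "grid", "voronoi", "contiguity"),
                      theta = 0.56, ...) {
  method <- match.arg(method)
  f <- switch(method, grid = delineate_grid, voronoi = delineate_voronoi,
              contiguity = delineate_contiguity, vorcon = delineate_vorcon)
  args <- list(...)
  args <- args[names(args) %in% names(formals(f))]
  do.call(f, c(list(hsm = hsm, theta = theta), args))
}

#' Export a patch landscape as paired rasters and a patch table
#'
#' Writes an integer patch-id raster (0 = matrix), an integer quality raster
#' (per-patch mean suitability scaled to 0-100, the layout patch-based
#' simulation tools consume) and a CSV patch table.
#'
#' @param pl A `patch_landscape`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default the delineation method).
#' @return Invisibly, the paths written.
#' @export
export_patch_landscape <- function(pl, dir, prefix = pl$method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id_r <- suit_raster(pl$patch_raster, pl$cell_size, pl$xll, pl$yll)
  q <- matrix(0, nrow(pl$patch_raster), ncol(pl$patch_raster))
  if (nrow(pl$table)) {
    scaled <- round_half_up(pl$table$mean_suit * 100)
    pos <- which(pl$patch_raster > 0)
    q[pos] <- scaled[pl$patch_raster[pos]]
  }
  q[is.na(pl$patch_raster)] <- NA
  q_r <- suit_raster(q, pl$cell_size, pl$xll, pl$yll)
  paths <- c(file.path(dir, paste0(prefix, "_patch_id.asc")),
             file.path(dir, paste0(prefix, "_quality.asc")),
             file.path(dir, paste0(prefix, "_patches.csv")))
  write_ascii_raster(id_r, paths[1])
  write_ascii_raster(q_r, paths[2])
  utils::write.csv(pl$table, paths[3], row.names = FALSE)
  invisible(paths)
}

# list of matrix cell indices per patch id
patch_cells <- function(pl) {
  pos <- which(pl$patch_raster > 0)
  split(pos, pl$patch_raster[pos])
}
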