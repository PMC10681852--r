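#' Minimum convex polygon around presence points
#'
#' Convex hull of the point set, the standard minimum-convex-polygon range
#' estimate.
#'
#' @param points n x 2 matrix (or data frame with `x`, `y`) of coordinates.
#' @return m x 2 matrix of hull vertices in counter-clockwise order.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- as.matrix(if (is.data.frame(points)) points[, c("x", "y")] else points)
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3) stop("need at least 3 distinct points", call. = FALSE)
  h <- grDevices::chull(pts)          # clockwise indices
  hull <- pts[rev(h), , drop = FALSE] # counter-clockwise
  if (polygon_area(hull) <= 0)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  dimnames(hull) <- list(NULL, c("x", "y"))
  hull
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(n, seq_len(n - 1))
  abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
}

# Separating-axis test: does a convex polygon intersect an axis-aligned
# rectangle? Touching boundaries count as intersecting.
convex_polygon_intersects_rect <- function(poly, rect) {
  xs <- poly[, 1]; ys <- poly[, 2]
  if (max(xs) < rect[1] || min(xs) > rect[3] ||
      max(ys) < rect[2] || min(ys) > rect[4]) return(FALSE)
  corners <- rbind(c(rect[1], rect[2]), c(rect[3], rect[2]),
                   c(rect[3], rect[4]), c(rect[1], rect[4]))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ax <- -(b[2] - a[2]); ay <- b[1] - a[1]      # outward-ish edge normal
    pp <- xs * ax + ys * ay
    pc <- corners[, 1] * ax + corners[, 2] * ay
    if (max(pc) < min(pp) || min(pc) > max(pp)) return(FALSE)
  }
  TRUE
}

#' Fishnet cells intersecting a convex polygon
#'
#' @param fn A [make_fishnet] grid.
#' @param poly m x 2 matrix of convex-polygon vertices.
#' @return Sorted integer cell ids.
#' @export
fishnet_cells_intersecting <- function(fn, poly) {
  ids <- seq_len(fishnet_n_cells(fn))
  rects <- fishnet_cell_rect(fn, ids)
  hit <- vapply(ids, function(i)
    convex_polygon_intersects_rect(poly, rects[i, ]), logical(1))
  ids[hit]
}

#' Observed ranges per timestep from cumulative presences
#'
#' For each period, all presences up to the period's end year are pooled
#' (ranges are cumulative, so the observed range never shrinks), a minimum
#' convex polygon is fitted, and two comparators are derived on the
#' evaluation grid: `obs_range` (cells intersecting the polygon) and
#' `obs_presences` (cells containing presence records). When a period has
#' fewer than three non-collinear points the range falls back to the
#' presence cells, with a warning.
#'
#' @param presences Data frame with columns `x`, `y`, `year`.
#' @param period_ends Integer vector of period end years (ascending).
#' @param fishnet A [make_fishnet] evaluation grid.
#' @return A list of class `range_observation` per timestep with elements
#'   `end_year`, `n`, `mcp`, `obs_range`, `obs_presences`; timesteps with no
#'   presences are flagged `empty = TRUE` and skipped downstream.
#' @export
observed_ranges <- function(presences, period_ends, fishnet) {
  stopifnot(all(diff(period_ends) > 0))
  out <- lapply(period_ends, function(end) {
    sub <- presences[presences$year <= end, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no presences up to year ", end, "; timestep skipped",
              call. = FALSE)
      return(list(end_year = end, n = 0L, empty = TRUE,
                  mcp = NULL, obs_range = integer(0), obs_presences = integer(0)))
    }
    pres_cells <- sort(unique(stats::na.omit(
      fishnet_cell_of(fishnet, cbind(sub$x, sub$y)))))
    mcp <- tryCatch(minimum_convex_polygon(sub[, c("x", "y")]),
                    error = function(e) NULL)
    if (is.null(mcp)) {
      warning("degenerate point set up to year ", end,
              "; using presence cells as the range", call. = FALSE)
      rng <- pres_cells
    } else {
      rng <- fishnet_cells_intersecting(fishnet, mcp)
    }
    list(end_year = end, n = nrow(sub), empty = FALSE, mcp = mcp,
         obs_range = rng, obs_presences = intersect(pres_cells, union(rng, pres_cells)))
  })
  structure(out, class = "range_observation")
}

#' Fishnet cells intersected by occupied patches
#'
#' A cell belongs to the simulated range if it contains at least one raster
#' cell centre of at least one occupied patch.
#'
#' @param occupied_ids Integer ids of occupied patches.
#' @param landscape A `patch_landscape`.
#' @param fishnet A [make_fishnet] grid.
#' @return Sorted integer cell ids.
#' @export
simulated_range_cells <- function(occupied_ids, landscape, fishnet) {
  if (!length(occupied_ids)) return(integer(0))
  geom <- suit_raster(landscape$patch_raster, landscape$cell_size,
                      landscape$xll, landscape$yll)
  pos <- which(landscape$patch_raster %in% occupied_ids)
  if (!length(pos)) return(integer(0))
  centres <- cell_centres(geom)[pos, , drop = FALSE]
  sort(unique(stats::na.omit(fishnet_cell_of(fishnet, centres))))
}

#' True Skill Statistic for a binary range prediction
#'
#' Standard definitions: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, `TSS = sensitivity + specificity - 1`. Computed over the
#' supplied evaluation region (true negatives exist only inside it).
#'
#' @param predicted Integer cell ids predicted occupied.
#' @param observed Integer cell ids observed occupied.
#' @param region Integer cell ids of the evaluation region.
#' @return One-row data frame: `TP`, `FP`, `FN`, `TN`, `sensitivity`,
#'   `specificity`, `tss`. Components with empty denominators are `NA`.
#' @export
true_skill_statistic <- function(predicted, observed, region) {
  predicted <- intersect(predicted, region)
  observed <- intersect(observed, region)
  tp <- length(intersect(predicted, observed))
  fp <- length(setdiff(predicted, observed))
  fn <- length(setdiff(observed, predicted))
  tn <- length(region) - tp - fp - fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  data.frame(TP = tp, FP = fp, FN = fn, TN = tn,
             sensitivity = sens, specificity = spec,
             tss = sens + spec - 1)
}

#' Score a simulated occupancy series against observed ranges
#'
#' At each matched timestep the simulated range (fishnet cells intersecting
#' patches whose mean occupancy meets the threshold) is compared to both
#' comparators (`obs_range` and `obs_presences`) with the True Skill
#' Statistic, and summarised per comparator as mean, SD, min and max.
#'
#' @param occupancy An `occupancy_series` from [run_simulation].
#' @param landscape The `patch_landscape` that was simulated.
#' @param observations A [observed_ranges] sequence of equal length.
#' @param fishnet The evaluation grid.
#' @param region Cell ids of the evaluation region (default: all cells).
#' @return A list of class `eval_result`: `per_timestep` data frame and
#'   `summary` data frame (one row per comparator).
#' @export
evaluate_timeseries <- function(occupancy, landscape, observations, fishnet,
                                region = seq_len(fishnet_n_cells(fishnet))) {
  nts <- nrow(occupancy$occupied)
  if (nts != length(observations))
    stop("number of simulated and observed timesteps differ", call. = FALSE)
  rows <- list()
  for (t in seq_len(nts)) {
    obs <- observations[[t]]
    if (isTRUE(obs$empty)) next
    occ_ids <- which(occupancy$occupied[t, ])
    sim_cells <- simulated_range_cells(occ_ids, landscape, fishnet)
    for (comp in c("obs_range", "obs_presences")) {
      r <- true_skill_statistic(sim_cells, obs[[comp]], region)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(timestep = t, comparator = comp,
                         n_sim_cells = length(sim_cells),
                         n_obs_cells = length(obs[[comp]])), r)
    }
  }
  per <- do.call(rbind, rows)
  # timesteps with an undefined component (no observed presences, or no
  # observed absences, in the region) stay NA per-timestep and are excluded
  # from the summary; n_used reports how many timesteps contributed
  summ <- do.call(rbind, lapply(split(per, per$comparator), function(d) {
    z <- d$tss[is.finite(d$tss)]
    data.frame(comparator = d$comparator[1], n_used = length(z),
               mean = mean(z), sd = stats::sd(z),
               min = suppressWarnings(min(z)), max = suppressWarnings(max(z)))
  }))
  rownames(summ) <- NULL
  structure(list(per_timestep = per, summary = summ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Threshold maximising sensitivity + specificity (maxSSS)
#'
#' Scans every observed score as a candidate threshold (classification rule:
#' score >= threshold is a predicted presence) and returns the one
#' maximising sensitivity + specificity; ties break toward the smaller
#' threshold. The presence-only analogue of the maxSSS criterion used to
#' pick a suitability cut-off.
#'
#' @param presence_scores Suitability scores at presences.
#' @param background_scores Suitability scores at background points.
#' @return The selected threshold (a value from the score union).
#' @export
maxsss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores))
    stop("both score vectors must be non-empty", call. = FALSE)
  cand <- sort(unique(c(presence_scores, background_scores)))
  best <- -Inf; best_t <- cand[1]
  for (t in cand) {
    sens <- mean(presence_scores >= t)
    spec <- mean(background_scores < t)
    if (sens + spec > best + 1e-12) { best <- sens + spec; best_t <- t }
  }
  best_t
}

#' Jaccard similarity of two cell sets
#' @param a,b Integer cell id vectors.
#' @return |a n b| / |a u b| (1 when both empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Sensitivity analysis over the user-defined movement parameters
#'
#' Re-runs the simulation with perceptual range, directional persistence and
#' the step budget each varied by +/-10 percent (six perturbed
#' configurations plus the base), under common seeds, and reports the
#' Jaccard similarity of each run's final-checkpoint occupied cell set to
#' the base run. A zero-perturbation control is the base row (Jaccard 1).
#'
#' @param base_config A [sim_config].
#' @param landscape A `patch_landscape`.
#' @param cost Cost raster.
#' @param init_patches Initial patch ids.
#' @param fishnet Evaluation grid.
#' @param delta Relative perturbation (default 0.1).
#' @return Data frame with one row per configuration: `parameter`,
#'   `direction`, `value`, `n_cells`, `jaccard_vs_base`; the cell sets are
#'   attached as the `cells` attribute.
#' @export
sensitivity_analysis <- function(base_config, landscape, cost, init_patches,
                                 fishnet, delta = 0.1) {
  run_cells <- function(cfg) {
    occ <- run_simulation(landscape, cost, init_patches, cfg)
    simulated_range_cells(which(occ$occupied[nrow(occ$occupied), ]),
                          landscape, fishnet)
  }
  params <- c("perceptual_range", "directional_persistence", "max_steps")
  # fix the duration from the base config so all runs share checkpoints
  base_cfg <- base_config
  if (is.null(base_cfg$total_years)) {
    occ0 <- run_simulation(landscape, cost, init_patches, base_cfg)
    base_cfg$total_years <- occ0$total_years
  }
  base_cells <- run_cells(base_cfg)
  rows <- data.frame(parameter = "base", direction = 0,
                     value = NA_real_, n_cells = length(base_cells),
                     jaccard_vs_base = 1)
  cells <- list(base = base_cells)
  for (p in params) for (s in c(-1, 1)) {
    cfg <- base_cfg
    cfg[[p]] <- base_cfg[[p]] * (1 + s * delta)
    cc <- run_cells(cfg)
    key <- sprintf("%s%+d", p, s)
    cells[[key]] <- cc
    rows <- rbind(rows, data.frame(parameter = p, direction = s,
                                   value = cfg[[p]], n_cells = length(cc),
                                   jaccard_vs_base = jaccard(cc, base_cells)))
  }
  attr(rows, "cells") <- cells
  rows
}
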