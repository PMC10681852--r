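#' Read a pipeline configuration file
#'
#' Accepts YAML (when the `yaml` package is installed) or JSON. The file is
#' a nested list mirroring the arguments of [run_evaluate_historic] /
#' [run_predict_novel]: sections `delineation` (method, theta, density,
#' min_distance), `simulation` (fields of [sim_config]) and `evaluation`
#' (period_ends, fishnet_cell), plus `seed` and `mode`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# one seed per stage, derived from the master seed by fixed offsets so a
# single stage can be re-run reproducibly
stage_seed <- function(seed, stage, index = 0L) {
  offsets <- c(delineate = 1000L, simulate = 2000L, presence = 3000L)
  as.integer(seed + offsets[[stage]] + index)
}

#' Evaluate hybrid models against historic spread (Steps 2-4)
#'
#' For each requested delineation method: generalise the suitability map
#' into patches, derive the cost surface by integer scaling and inversion,
#' initialise occupancy from a buffer around the centroid of the
#' first-period presences, simulate replicate spread, and score the
#' simulated range against both observed-range comparators with the True
#' Skill Statistic at matched timesteps.
#'
#' @param hsm A [suit_raster].
#' @param presences Data frame with `x`, `y`, `year`.
#' @param methods Delineation methods to run.
#' @param theta Suitability threshold (default 0.56).
#' @param density,min_distance Voronoi point-sampling parameters.
#' @param sim Simulation configuration ([sim_config]); its
#'   `n_report_timesteps` is forced to the number of observation periods,
#'   and its seed is derived from `seed`.
#' @param period_ends End years of the observation periods.
#' @param fishnet_cell Evaluation-grid cell size in metres (default 10 km).
#' @param init_radius Initialisation buffer radius in metres (default 10 km).
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param out_dir Optional directory; if given, summary/per-timestep CSVs,
#'   patch exports and a provenance log are written.
#' @return A list of class `historic_bundle`: `summary` (method x comparator
#'   rows), `per_timestep`, `landscapes`, `occupancy`, `observations`,
#'   `fishnet`, `provenance`.
#' @export
run_evaluate_historic <- function(hsm, presences,
                                  methods = c("grid", "voronoi",
                                              "contiguity", "vorcon"),
                                  theta = 0.56, density = 1,
                                  min_distance = 150,
                                  sim = sim_config(),
                                  period_ends, fishnet_cell = 10000,
                                  init_radius = 10000,
                                  seed = 1L, out_dir = NULL) {
  if (length(period_ends) < 2)
    stop("presences must span at least two periods", call. = FALSE)
  nr <- nrow(hsm$values); nc <- ncol(hsm$values)
  fn <- make_fishnet(hsm$xll, hsm$yll,
                     hsm$xll + nc * hsm$cell_size,
                     hsm$yll + nr * hsm$cell_size, fishnet_cell)
  obs <- observed_ranges(presences, period_ends, fn)
  cost <- invert_to_cost(scale_suitability(hsm))
  first <- presences[presences$year <= period_ends[1], , drop = FALSE]

  sim$n_report_timesteps <- length(period_ends)
  landscapes <- list(); occupancy <- list()
  summary_rows <- list(); per_rows <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    pl <- delineate(hsm, m, theta,
                    density = density, min_distance = min_distance,
                    seed = stage_seed(seed, "delineate", i))
    cfg <- sim
    cfg$seed <- stage_seed(seed, "simulate", i)
    init <- init_from_buffer(pl, first, init_radius)
    occ <- run_simulation(pl, cost, init, cfg)
    ev <- evaluate_timeseries(occ, pl, obs, fn)
    landscapes[[m]] <- pl
    occupancy[[m]] <- occ
    summary_rows[[m]] <- cbind(method = m, ev$summary)
    per_rows[[m]] <- cbind(method = m, ev$per_timestep)
  }
  summary <- do.call(rbind, summary_rows); rownames(summary) <- NULL
  per <- do.call(rbind, per_rows); rownames(per) <- NULL
  prov <- list(seed = seed, theta = theta, density = density,
               min_distance = min_distance, period_ends = period_ends,
               fishnet_cell = fishnet_cell, methods = methods,
               sim = unclass(sim),
               package_version = as.character(utils::packageVersion("patchspread")))
  bundle <- structure(list(summary = summary, per_timestep = per,
                           landscapes = landscapes, occupancy = occupancy,
                           observations = obs, fishnet = fn, cost = cost,
                           provenance = prov),
                      class = "historic_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "tss_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(per, file.path(out_dir, "tss_per_timestep.csv"),
                     row.names = FALSE)
    for (m in names(landscapes))
      export_patch_landscape(landscapes[[m]], out_dir, m)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}

#' Predict spread in a novel region (Step 5)
#'
#' Delineates the novel-region suitability map with the Vor-Con method,
#' initialises occupancy from evaluation-grid cells intersecting presence
#' records, simulates spread, and reports occupied cell sets per timestep
#' plus a relative colonisation-order table (first checkpoint at which each
#' patch's mean occupancy meets the threshold).
#'
#' @inheritParams run_evaluate_historic
#' @param n_timesteps Reporting checkpoints (default 10).
#' @return A list of class `novel_bundle`: `landscape`, `occupancy`,
#'   `range_cells` (list per timestep), `colonisation_order` data frame,
#'   `fishnet`, `provenance`.
#' @export
run_predict_novel <- function(hsm, presences, theta = 0.56, density = 1,
                              min_distance = 150, sim = sim_config(),
                              n_timesteps = 10, fishnet_cell = 10000,
                              seed = 1L, out_dir = NULL) {
  nr <- nrow(hsm$values); nc <- ncol(hsm$values)
  fn <- make_fishnet(hsm$xll, hsm$yll,
                     hsm$xll + nc * hsm$cell_size,
                     hsm$yll + nr * hsm$cell_size, fishnet_cell)
  cost <- invert_to_cost(scale_suitability(hsm))
  pl <- delineate_vorcon(hsm, theta, density = density,
                         min_distance = min_distance,
                         seed = stage_seed(seed, "delineate"))
  init <- init_from_cells(pl, presences, fn)
  cfg <- sim
  cfg$n_report_timesteps <- n_timesteps
  cfg$seed <- stage_seed(seed, "simulate")
  occ <- run_simulation(pl, cost, init, cfg)
  range_cells <- lapply(seq_len(nrow(occ$occupied)), function(t)
    simulated_range_cells(which(occ$occupied[t, ]), pl, fn))
  first_ts <- apply(occ$mean_occupancy >= cfg$occupancy_threshold, 2,
                    function(z) if (any(z)) which(z)[1] else NA_integer_)
  order_tab <- data.frame(patch_id = pl$table$id,
                          area_km2 = pl$table$area_km2,
                          first_timestep = first_ts)
  order_tab <- order_tab[order(order_tab$first_timestep,
                               order_tab$patch_id), ]
  prov <- list(seed = seed, theta = theta, n_timesteps = n_timesteps,
               fishnet_cell = fishnet_cell, sim = unclass(sim))
  bundle <- structure(list(landscape = pl, occupancy = occ,
                           range_cells = range_cells,
                           colonisation_order = order_tab,
                           fishnet = fn, cost = cost, provenance = prov),
                      class = "novel_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_patch_landscape(pl, out_dir, "vorcon")
    utils::write.csv(order_tab, file.path(out_dir, "colonisation_order.csv"),
                     row.names = FALSE)
    occ_df <- do.call(rbind, lapply(seq_along(range_cells), function(t)
      if (length(range_cells[[t]]))
        data.frame(timestep = t, cell_id = range_cells[[t]])))
    utils::write.csv(occ_df, file.path(out_dir, "range_cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
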