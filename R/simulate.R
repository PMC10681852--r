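#' Simulation configuration
#'
#' Parameter set for the patch-occupancy spread simulation. Defaults follow
#' the standardised parameterisation used for a generalist ungulate:
#' demographic rates fixed at 1 so density dependence alone regulates
#' output, and movement parameters (perceptual range 400 m, directional
#' persistence 5, 200-step budget) describing a correlated random walk over
#' the cost surface.
#'
#' @param fecundity_max Maximum offspring per adult per year at low density.
#' @param survival_juv,survival_disp,survival_adult Stage survival
#'   probabilities (juvenile, disperser, adult).
#' @param dd_b Strength of density dependence `b` in the exponential decay
#'   `x0 * exp(-b * N)`; the conventional report is its inverse `1/b` = 1.
#' @param dd_on_survival Apply density dependence to survival as well as
#'   fecundity? Default `FALSE`: with `b = 1` a single resident would push
#'   survival to `exp(-1)`, contradicting the intended near-zero local
#'   extinction probability, so by default the decay acts on fecundity only.
#' @param max_age Maximum adult age in years.
#' @param repro_prob Probability an adult reproduces in a year.
#' @param emigration_prob Probability a disperser emigrates (`Dy`).
#' @param perceptual_range Perceptual range in metres (PR).
#' @param directional_persistence Correlated-walk strength (DP).
#' @param settle_alpha,settle_beta Slope and inflexion of the logistic
#'   settlement probability in `N/K`.
#' @param max_steps Path-length budget in cardinal-step units; with 100 m
#'   cells, 200 steps bounds Euclidean displacement at 20 km.
#' @param k_max Carrying capacity of one km^2 of fully suitable habitat
#'   (individuals); `K = max(1, round(area * mean_suit * k_max))`.
#' @param replicates Number of replicate simulations.
#' @param occupancy_threshold Mean-occupancy threshold above which a patch
#'   counts as occupied (0.7 = 7 of 10 replicates).
#' @param n_report_timesteps Number of evenly spaced reporting checkpoints.
#' @param total_years Simulation length in years; `NULL` = auto (a pilot
#'   replicate runs until every patch is occupied, capped at `max_years`).
#' @param max_years Hard cap for the auto duration (default 600).
#' @param seed Base RNG seed; replicate r uses `seed + r - 1`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fecundity_max = 1.0,
                       survival_juv = 1.0, survival_disp = 1.0,
                       survival_adult = 1.0,
                       dd_b = 1.0, dd_on_survival = FALSE,
                       max_age = 1000, repro_prob = 1.0,
                       emigration_prob = 1.0,
                       perceptual_range = 400,
                       directional_persistence = 5,
                       settle_alpha = -100, settle_beta = 1.0,
                       max_steps = 200, k_max = 1.0,
                       replicates = 10, occupancy_threshold = 0.7,
                       n_report_timesteps = 6,
                       total_years = NULL, max_years = 600,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(survival_juv, survival_disp, survival_adult, repro_prob,
             emigration_prob, occupancy_threshold)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Exponential-decay density dependence
#'
#' `x0 * exp(-b * N)`: the maximum rate at low density decays with the total
#' number of individuals `N` in the local population.
#'
#' @param x0 Maximum rate at low density (>= 0).
#' @param b Strength of density dependence (>= 0).
#' @param N Total individuals in the patch (>= 0).
#' @return The density-adjusted rate.
#' @export
density_dependent_rate <- function(x0, b, N) {
  stopifnot(all(x0 >= 0), all(b >= 0), all(N >= 0))
  x0 * exp(-b * N)
}

#' Patch carrying capacity
#'
#' Carrying capacity is linear in patch area times mean suitability, floored
#' at one individual so every retained patch can hold a resident.
#'
#' @param area_km2 Patch area(s), km^2.
#' @param mean_suit Mean continuous suitability in `[0, 1]`.
#' @param k_max Individuals supported by 1 km^2 of fully suitable habitat.
#' @return Integer carrying capacities.
#' @export
patch_carrying_capacity <- function(area_km2, mean_suit, k_max = 1.0) {
  pmax(1, round_half_up(area_km2 * mean_suit * k_max))
}

#' Logistic settlement probability
#'
#' `1 / (1 + exp(-alpha * (N/K - beta)))`. With the default steep negative
#' slope (`alpha = -100`) and inflexion at `beta = 1`, dispersers settle
#' almost surely in patches below carrying capacity, with probability 0.5
#' exactly at capacity, and almost never above it.
#'
#' @param N Current individuals in the candidate patch.
#' @param K Patch carrying capacity (>= 1).
#' @param alpha Slope (negative for the step-down shape).
#' @param beta Inflexion point on the `N/K` axis.
#' @return Settlement probability.
#' @export
settlement_probability <- function(N, K, alpha = -100, beta = 1.0) {
  stopifnot(all(K >= 1))
  mapply(function(n, k) .settle_prob_cpp(n, k, alpha, beta), N, K)
}

#' Perceived cost of moving in one direction
#'
#' Inverse-distance-weighted mean of cell costs along the directional ray up
#' to `pr_cells` cells (weights `1/d`), truncated at the map edge or at
#' nodata; `Inf` if even the adjacent cell is off-map (direction disallowed).
#'
#' @param cost A cost [suit_raster] (`NA` = off-map).
#' @param row,col Current cell (1-based matrix indices).
#' @param dir Direction 1..8 = N, NE, E, SE, S, SW, W, NW.
#' @param pr_cells Perceptual range in cells (>= 1).
#' @return Perceived cost (positive, possibly `Inf`).
#' @export
effective_cost <- function(cost, row, col, dir, pr_cells) {
  stopifnot(pr_cells >= 1, dir %in% 1:8)
  .eff_cost_cpp(cost$values, row, col, dir, pr_cells)
}

#' Step-direction probabilities for a disperser
#'
#' Each direction's weight is `DP^((4-k)/4) / effective_cost(dir)`, where
#' `k` is the number of 45-degree increments between the direction and the
#' current heading (straight ahead: `DP`, right angle: `sqrt(DP)`, reverse:
#' 1). With no heading yet the persistence factor is 1 everywhere.
#' Disallowed (off-map) directions get weight 0.
#'
#' @param cost A cost [suit_raster].
#' @param row,col Current cell.
#' @param heading Previous step direction 1..8, or 0 for none.
#' @param config A [sim_config] (uses `directional_persistence`,
#'   `perceptual_range`).
#' @return Length-8 vector of probabilities (sums to 1), or all zero when
#'   the disperser is fully enclosed.
#' @export
step_weights <- function(cost, row, col, heading, config = sim_config()) {
  pr <- pr_in_cells(config, cost$cell_size)
  w <- .step_weights_cpp(cost$values, row, col, heading,
                         config$directional_persistence, pr)
  s <- sum(w)
  if (s > 0) w / s else w
}

# perceptual range in whole cells (truncating division, floor at 1)
pr_in_cells <- function(config, cell_size) {
  max(1L, as.integer(floor(config$perceptual_range / cell_size)))
}

#' Maximum possible dispersal displacement
#'
#' The straight cardinal path exhausts the step budget at exactly
#' `max_steps * cell_size` metres; diagonal steps consume `sqrt(2)` budget
#' units, so no path can exceed this Euclidean displacement.
#'
#' @param config A [sim_config].
#' @param cell_size Cell edge in metres.
#' @return Maximum Euclidean displacement in metres.
#' @export
max_dispersal_distance <- function(config, cell_size) {
  config$max_steps * cell_size
}

#' Annual reproduction in occupied patches
#'
#' Each adult produces a Poisson-distributed number of offspring with
#' density-dependent mean `fecundity_max * exp(-b * N)`, thinned by the
#' reproduction probability. Patches without adults produce nothing.
#'
#' @param adults Integer vector of adults per patch.
#' @param N Total individuals per patch (enters the density dependence).
#' @param config A [sim_config].
#' @return Integer vector of juveniles per patch.
#' @export
reproduce <- function(adults, N, config = sim_config()) {
  rate <- density_dependent_rate(config$fecundity_max, config$dd_b, N)
  stats::rpois(length(adults), adults * config$repro_prob * rate)
}

# --- simulation environment -------------------------------------------------

#' Precompute the static arena for simulation
#'
#' Bundles the patch-id matrix, cost matrix, per-patch cell lists and
#' carrying capacities so replicate runs share the same arena.
#'
#' @param landscape A `patch_landscape`.
#' @param cost A cost [suit_raster] on the same grid.
#' @param config A [sim_config].
#' @return A list of class `sim_env`.
#' @export
make_sim_env <- function(landscape, cost, config = sim_config()) {
  stopifnot(identical(dim(landscape$patch_raster), dim(cost$values)))
  tab <- landscape$table
  K <- patch_carrying_capacity(tab$area_km2, tab$mean_suit, config$k_max)
  pm <- landscape$patch_raster
  structure(list(patch = pm, cost = cost$values,
                 cells = patch_cells(landscape),
                 K = as.numeric(K), n_patch = nrow(tab),
                 cell_size = landscape$cell_size,
                 pr_cells = pr_in_cells(config, landscape$cell_size)),
            class = "sim_env")
}

#' Initial population state
#'
#' Seeded patches start at carrying capacity (`N = K` adults).
#'
#' @param env A [make_sim_env] arena.
#' @param init_ids Patch ids initially occupied.
#' @param total_years Years the state must accommodate.
#' @return A list of class `sim_state`.
#' @export
init_state <- function(env, init_ids, total_years) {
  if (!length(init_ids)) stop("initial patch set is empty", call. = FALSE)
  if (!all(init_ids %in% seq_len(env$n_patch)))
    stop("initial patch id not in landscape", call. = FALSE)
  cohorts <- matrix(0, env$n_patch, total_years + 2L)  # col y+1 = adults gained in year y
  cohorts[init_ids, 1L] <- env$K[init_ids]
  structure(list(cohorts = cohorts, year = 0L,
                 log = data.frame(year = integer(0), emigrated = integer(0),
                                  settled = integer(0), died = integer(0))),
            class = "sim_state")
}

state_adults <- function(state) rowSums(state$cohorts)

#' Advance the population by one year
#'
#' Event order: reproduction in occupied patches (Poisson offspring with
#' density-dependent mean), juvenile survival and development into
#' dispersers, obligate emigration, stochastic transfer over the cost
#' surface with per-step settlement in non-natal patches below capacity,
#' then ageing. Settled dispersers join the destination as adults from the
#' next year. Every emigrant ends the year settled or dead (conservation).
#'
#' @param state A [init_state] population state.
#' @param env A [make_sim_env] arena.
#' @param config A [sim_config].
#' @return The updated `sim_state`.
#' @export
simulate_year <- function(state, env, config = sim_config()) {
  year <- state$year + 1L
  adults <- state_adults(state)
  N <- adults
  dd <- exp(-config$dd_b * N)
  sj <- config$survival_juv * if (config$dd_on_survival) dd else 1
  sy <- config$survival_disp * if (config$dd_on_survival) dd else 1

  juv <- reproduce(adults, N, config)
  disp <- stats::rbinom(env$n_patch, juv, pmin(1, sj))
  emig <- stats::rbinom(env$n_patch, disp, config$emigration_prob)
  stay <- disp - emig
  surv_em <- stats::rbinom(env$n_patch, emig, pmin(1, sy))
  died_pre <- sum(emig) - sum(surv_em)

  settled_by_patch <- numeric(env$n_patch)
  n_set <- 0L; n_died <- died_pre
  if (sum(surv_em) > 0) {
    natal <- rep(seq_len(env$n_patch), surv_em)
    starts <- integer(length(natal))
    pos <- 1L
    for (p in which(surv_em > 0)) {
      cells <- env$cells[[as.character(p)]]
      k <- surv_em[p]
      starts[pos:(pos + k - 1L)] <- cells[sample.int(length(cells), k, replace = TRUE)]
      pos <- pos + k
    }
    nr <- nrow(env$patch)
    srow <- ((starts - 1L) %% nr) + 1L
    scol <- ((starts - 1L) %/% nr) + 1L
    res <- .transfer_batch_cpp(env$patch, env$cost, natal, srow, scol,
                               N + stay, env$K,
                               config$directional_persistence, env$pr_cells,
                               config$max_steps,
                               config$settle_alpha, config$settle_beta)
    ok <- res$outcome > 0
    n_set <- sum(ok)
    n_died <- n_died + sum(!ok)
    if (n_set) settled_by_patch <- tabulate(res$outcome[ok], env$n_patch)
  }

  cohorts <- state$cohorts
  # settlers and non-emigrant dispersers become adults next year (cohort = this year)
  cohorts[, year + 1L] <- cohorts[, year + 1L] + settled_by_patch + stay
  # adult survival and maximum age
  if (config$survival_adult < 1) {
    live <- which(cohorts > 0)
    cohorts[live] <- stats::rbinom(length(live), cohorts[live],
                                   config$survival_adult)
  }
  # a cohort entering adulthood (age 2) in year y has age (year - y) + 2
  old <- which(year - (seq_len(ncol(cohorts)) - 1L) + 2L > config$max_age)
  if (length(old)) cohorts[, old] <- 0

  state$cohorts <- cohorts
  state$year <- year
  state$log <- rbind(state$log,
                     data.frame(year = year, emigrated = sum(emig),
                                settled = n_set, died = n_died))
  state
}

#' Run the replicate patch-occupancy simulation
#'
#' Runs `config$replicates` replicates (replicate r seeded with
#' `config$seed + r - 1`) for `total_years` years, recording binary patch
#' occupancy (any adults present) at `n_report_timesteps` evenly spaced
#' checkpoints, and reduces to mean occupancy with the occupancy threshold.
#' When `total_years` is `NULL`, a pilot replicate first runs until every
#' patch is occupied (capped at `config$max_years`) to fix the duration, so
#' the final checkpoint sits near complete occupation.
#'
#' @param landscape A `patch_landscape`.
#' @param cost A cost [suit_raster] on the same grid.
#' @param init_patches Integer ids of initially occupied patches.
#' @param config A [sim_config].
#' @return An `occupancy_series`: `occupancy` array (replicate x timestep x
#'   patch), `mean_occupancy` (timestep x patch), `occupied` (logical,
#'   timestep x patch, mean >= threshold), `checkpoint_years`, and
#'   per-replicate conservation `logs`.
#' @export
run_simulation <- function(landscape, cost, init_patches, config = sim_config()) {
  env <- make_sim_env(landscape, cost, config)
  if (!length(init_patches) || !all(init_patches %in% seq_len(env$n_patch)))
    stop("init_patches must be a non-empty subset of landscape patch ids",
         call. = FALSE)
  total <- config$total_years
  if (is.null(total)) {
    set.seed(config$seed)
    st <- init_state(env, init_patches, config$max_years)
    total <- config$max_years
    for (y in seq_len(config$max_years)) {
      st <- simulate_year(st, env, config)
      if (all(state_adults(st) > 0)) { total <- y; break }
    }
  }
  nts <- config$n_report_timesteps
  checkpoints <- unique(pmax(1L, as.integer(round(seq_len(nts) * total / nts))))
  nts <- length(checkpoints)

  occ <- array(0L, dim = c(config$replicates, nts, env$n_patch))
  logs <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(config$seed + r - 1L)
    st <- init_state(env, init_patches, total)
    ci <- 1L
    for (y in seq_len(total)) {
      st <- simulate_year(st, env, config)
      if (ci <= nts && y == checkpoints[ci]) {
        occ[r, ci, ] <- as.integer(state_adults(st) > 0)
        ci <- ci + 1L
      }
    }
    logs[[r]] <- st$log
  }
  mean_occ <- apply(occ, c(2, 3), mean)
  structure(list(occupancy = occ, mean_occupancy = mean_occ,
                 occupied = mean_occ >= config$occupancy_threshold,
                 checkpoint_years = checkpoints, total_years = total,
                 threshold = config$occupancy_threshold,
                 init_patches = init_patches, logs = logs),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("<occupancy_series> %d replicates x %d checkpoints x %d patches (%d years)\n",
              dim(x$occupancy)[1], dim(x$occupancy)[2], dim(x$occupancy)[3],
              x$total_years))
  cat("  occupied patches per checkpoint:",
      paste(rowSums(x$occupied), collapse = " "), "\n")
  invisible(x)
}

#' Transfer a single disperser (exposed for testing and diagnostics)
#'
#' @param env A [make_sim_env] arena.
#' @param natal Natal patch id.
#' @param start_cell Matrix cell index of the start position (default: a
#'   uniformly drawn natal-patch cell).
#' @param config A [sim_config].
#' @param N Per-patch abundance used for settlement (default 0 everywhere).
#' @return List with `outcome` (settled patch id, 0 = died), `steps`, and
#'   `displacement_m`.
#' @export
transfer <- function(env, natal, start_cell = NULL, config = sim_config(),
                     N = numeric(env$n_patch)) {
  if (is.null(start_cell)) {
    cells <- env$cells[[as.character(natal)]]
    start_cell <- cells[sample.int(length(cells), 1L)]
  }
  nr <- nrow(env$patch)
  res <- .transfer_batch_cpp(env$patch, env$cost, natal,
                             ((start_cell - 1L) %% nr) + 1L,
                             ((start_cell - 1L) %/% nr) + 1L,
                             as.numeric(N), env$K,
                             config$directional_persistence, env$pr_cells,
                             config$max_steps,
                             config$settle_alpha, config$settle_beta)
  list(outcome = res$outcome[1], steps = res$steps[1],
       displacement_m = res$displacement[1] * env$cell_size)
}

# --- initialisation ---------------------------------------------------------

#' Initial patches from a buffer around the early observed range
#'
#' The centre is the centroid of the supplied presences (callers pass the
#' first-timestep records); patches with at least one cell centre within
#' `radius` of that centre are initialised.
#'
#' @param landscape A `patch_landscape`.
#' @param presences Data frame with columns `x`, `y` (metres).
#' @param radius Buffer radius in metres (default 10 km).
#' @return Integer patch ids.
#' @export
init_from_buffer <- function(landscape, presences, radius = 10000) {
  if (!nrow(presences)) stop("no presences supplied", call. = FALSE)
  ctr <- c(mean(presences$x), mean(presences$y))
  geom <- suit_raster(landscape$patch_raster, landscape$cell_size,
                      landscape$xll, landscape$yll)
  centres <- cell_centres(geom)
  pos <- which(landscape$patch_raster > 0)
  d2 <- (centres[pos, 1] - ctr[1])^2 + (centres[pos, 2] - ctr[2])^2
  ids <- sort(unique(landscape$patch_raster[pos][d2 <= radius^2]))
  if (!length(ids))
    stop("no patch within the initialisation buffer; simulation cannot start",
         call. = FALSE)
  ids
}

#' Initial patches from evaluation-grid cells containing presences
#'
#' Every patch with at least one cell centre inside a fishnet cell that
#' contains a presence record is initialised.
#'
#' @param landscape A `patch_landscape`.
#' @param presences Data frame with columns `x`, `y`.
#' @param fishnet A [make_fishnet] grid.
#' @return Integer patch ids.
#' @export
init_from_cells <- function(landscape, presences, fishnet) {
  if (!nrow(presences)) stop("no presences supplied", call. = FALSE)
  pcells <- unique(stats::na.omit(fishnet_cell_of(fishnet,
                                                  cbind(presences$x, presences$y))))
  geom <- suit_raster(landscape$patch_raster, landscape$cell_size,
                      landscape$xll, landscape$yll)
  centres <- cell_centres(geom)
  pos <- which(landscape$patch_raster > 0)
  cell_ids <- fishnet_cell_of(fishnet, centres[pos, , drop = FALSE])
  ids <- sort(unique(landscape$patch_raster[pos][cell_ids %in% pcells]))
  if (!length(ids))
    stop("no patch intersects a presence cell; simulation cannot start",
         call. = FALSE)
  ids
}
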