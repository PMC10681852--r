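#' Specification for a synthetic suitability surface
#'
#' Describes a spatially autocorrelated random suitability field (smoothed
#' white noise) with optional planted high-suitability blobs of known
#' footprint, emulating the patchy structure of a real habitat-suitability
#' map: discrete suitable clusters embedded in a low-suitability matrix.
#'
#' @param extent_km Length-2 numeric, extent in km (width = x, height = y).
#' @param cell_size Cell edge in metres (default 100).
#' @param autocorr_m Gaussian smoothing length in metres.
#' @param suit_mean,suit_sd Target mean and SD of the background field
#'   (clamped to `[0, 1]` after rescaling).
#' @param background_cap Optional upper cap applied to the background field
#'   before blobs are planted; set below the suitability threshold to
#'   guarantee that only planted blobs are suitable.
#' @param blobs Optional data frame with columns `x_km`, `y_km`,
#'   `radius_km`, `value` and optionally `edge_value`, `skirt_km`,
#'   `skirt_value`. Each blob is stamped after smoothing so its footprint
#'   (cell-centre distance <= radius) is exact: inside, suitability falls
#'   linearly (a cone) from `value` at the centre to `edge_value` at the
#'   radius (default `edge_value = value`, a flat disc); outside, an
#'   optional skirt decays from `skirt_value` just beyond the edge towards
#'   `suit_mean` with e-folding length `skirt_km`. Skirts keep the derived
#'   cost surface smooth across patch boundaries - real suitability maps
#'   have gradual edges, and step-function cost cliffs trap simulated
#'   dispersers inside patches.
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(extent_km, cell_size = 100, autocorr_m = 500,
                       suit_mean = 0.3, suit_sd = 0.1,
                       background_cap = NULL, blobs = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic generation",
                          call. = FALSE)
  n <- extent_km * 1000 / cell_size
  if (any(abs(n - round(n)) > 1e-9))
    stop("extent must be divisible by cell_size", call. = FALSE)
  structure(list(extent_km = extent_km, cell_size = cell_size,
                 autocorr_m = autocorr_m, suit_mean = suit_mean,
                 suit_sd = suit_sd, background_cap = background_cap,
                 blobs = blobs, seed = as.integer(seed)),
            class = "synth_spec")
}

# circular (FFT) convolution of white noise with a Gaussian kernel
smooth_noise <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_cells <= 0) return(z)
  gx <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = sigma_cells)
  gy <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = sigma_cells)
  k <- outer(gx, gy)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic suitability raster
#'
#' White noise is convolved with a Gaussian kernel of the requested
#' autocorrelation length, rescaled to the target mean and SD, clamped to
#' `[0, 1]` (and to `background_cap` if given), then any planted blobs are
#' stamped in. Identical specs give bit-identical rasters.
#'
#' @param spec A [synth_spec].
#' @return A [suit_raster].
#' @export
generate_hsm <- function(spec) {
  set.seed(spec$seed)
  cs <- spec$cell_size
  nc <- as.integer(round(spec$extent_km[1] * 1000 / cs))
  nr <- as.integer(round(spec$extent_km[2] * 1000 / cs))
  if (spec$suit_sd > 0) {
    f <- smooth_noise(nr, nc, spec$autocorr_m / cs)
    f <- (f - mean(f)) / stats::sd(f)
    v <- spec$suit_mean + spec$suit_sd * f
  } else {
    v <- matrix(spec$suit_mean, nr, nc)
  }
  v <- pmin(pmax(v, 0), 1)
  if (!is.null(spec$background_cap)) v <- pmin(v, spec$background_cap)
  r <- suit_raster(v, cs, 0, 0)
  if (!is.null(spec$blobs)) {
    centres <- cell_centres(r)
    vv <- as.vector(r$values)
    for (i in seq_len(nrow(spec$blobs))) {
      b <- spec$blobs[i, ]
      edge <- if (!is.null(b$edge_value) && !is.na(b$edge_value)) b$edge_value else b$value
      rad <- b$radius_km * 1000
      d <- sqrt((centres[, 1] - b$x_km * 1000)^2 +
                  (centres[, 2] - b$y_km * 1000)^2)
      inside <- d <= rad
      vv[inside] <- pmax(vv[inside],
                         edge + (b$value - edge) * (1 - d[inside] / rad))
      if (!is.null(b$skirt_km) && !is.na(b$skirt_km) && b$skirt_km > 0) {
        sv <- if (!is.null(b$skirt_value) && !is.na(b$skirt_value)) b$skirt_value else edge * 0.99
        out <- !inside
        vv[out] <- pmax(vv[out],
                        spec$suit_mean + (sv - spec$suit_mean) *
                          exp(-(d[out] - rad) / (b$skirt_km * 1000)))
      }
    }
    r$values <- matrix(pmin(pmax(vv, 0), 1), nr, nc)
  }
  r
}

# logical footprint of one blob row on the raster geometry
blob_footprint <- function(r, x_km, y_km, radius_km) {
  centres <- cell_centres(r)
  d2 <- (centres[, 1] - x_km * 1000)^2 + (centres[, 2] - y_km * 1000)^2
  m <- matrix(FALSE, nrow(r$values), ncol(r$values))
  m[d2 <= (radius_km * 1000)^2] <- TRUE
  m
}

#' Generate spatiotemporally clustered synthetic presences
#'
#' Emulates a radially expanding set of presence records: for each period,
#' points are drawn within a growing radius of the origin, biased towards
#' suitable cells (weight = suitability), jittered within the cell, and
#' stamped with the period's end year. Nodata cells are never sampled.
#'
#' @param hsm A [suit_raster].
#' @param origin Length-2 numeric `(x, y)` in metres; must be on-map.
#' @param n_per_period Integer vector: points per period.
#' @param period_ends Integer vector of period end years (same length).
#' @param spread_rate_km Radius growth per period (km).
#' @param initial_radius_km Radius for the first period (km).
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `y`, `year`.
#' @export
generate_presences <- function(hsm, origin, n_per_period, period_ends,
                               spread_rate_km = 2, initial_radius_km = 2,
                               seed = 1L) {
  stopifnot(length(n_per_period) == length(period_ends))
  set.seed(seed)
  centres <- cell_centres(hsm)
  ok <- !is.na(as.vector(hsm$values))
  w_all <- as.vector(hsm$values)
  d2 <- (centres[, 1] - origin[1])^2 + (centres[, 2] - origin[2])^2
  if (min(d2[ok]) > (2 * hsm$cell_size)^2)
    stop("origin is not on the mapped area", call. = FALSE)
  out <- list()
  for (i in seq_along(period_ends)) {
    radius <- (initial_radius_km + spread_rate_km * (i - 1)) * 1000
    idx <- which(ok & d2 <= radius^2)
    w <- w_all[idx]
    if (all(w <= 0)) w <- rep(1, length(idx))
    pick <- idx[sample.int(length(idx), n_per_period[i], replace = TRUE,
                           prob = w)]
    jit <- matrix(stats::runif(2 * length(pick), -0.5, 0.5), ncol = 2) *
      hsm$cell_size
    out[[i]] <- data.frame(x = centres[pick, 1] + jit[, 1],
                           y = centres[pick, 2] + jit[, 2],
                           year = period_ends[i])
  }
  do.call(rbind, out)
}

#' Canonical seeded benchmark fixtures
#'
#' Four self-contained landscapes with documented ground truth, used by the
#' test suite and usable as worked examples:
#' \describe{
#'   \item{two_patch_corridor}{A 0.3 x 1.3 km strip world: habitat block A
#'     (west, 3 x 3 cells at 0.65), a 5-cell-long corridor of sub-threshold
#'     but low-cost habitat (0.50), and habitat block B (east, 3 x 5 cells
#'     at 0.65). The whole map is walkable; the corridor is the only route
#'     between the patches. Ground truth: masks `A`, `B`, `corridor`.}
#'   \item{mega_patch}{A 60 x 10 km map holding one 50 x 2 km (100 km^2)
#'     uniform suitable block on a sub-threshold background - a single
#'     contiguous mega-patch spanning six 10-km evaluation cells.
#'     Presences cluster at the west end.}
#'   \item{archipelago}{A 20 x 20 km map with 20 medium-sized (~0.8 km^2)
#'     cone-profile blobs: one at the centre and 19 on a golden-angle
#'     spiral at graded distances (2.2-9 km), in a permeable matrix
#'     (suitability ~0.5, below threshold) with smooth blob skirts.}
#'   \item{uniform_matrix}{A uniform 5 x 5 km surface at suitability 0.3 -
#'     entirely below the 0.56 threshold, so no patches exist.}
#' }
#'
#' @param seed Integer seed (default 1); all randomness derives from it.
#' @return Named list of fixtures; each has `hsm`, `theta`, and
#'   fixture-specific ground-truth entries.
#' @export
fixtures <- function(seed = 1L) {
  theta <- 0.56
  fx <- list()

  # -- two_patch_corridor: A | 5-cell corridor | B, 3-row strip world
  v <- matrix(0.50, 3, 13)              # corridor value everywhere first
  v[, 1:3] <- 0.65                      # A
  v[, 9:13] <- 0.65                     # B
  hsm <- suit_raster(v, 100, 0, 0)
  A <- col(v) <= 3
  B <- col(v) >= 9
  fx$two_patch_corridor <- list(hsm = hsm, theta = theta, A = A, B = B,
                                corridor = !(A | B))

  # -- mega_patch: one 50 x 2 km block (100 km^2) on a hostile background
  spec <- synth_spec(c(60, 10), suit_mean = 0.3, suit_sd = 0.05,
                     background_cap = 0.5, seed = seed + 1L)
  hsm <- generate_hsm(spec)
  block <- matrix(FALSE, nrow(hsm$values), ncol(hsm$values))
  centres <- cell_centres(hsm)
  block[centres[, 1] > 4000 & centres[, 1] < 54000 &
          centres[, 2] > 4000 & centres[, 2] < 6000] <- TRUE
  hsm$values[block] <- 0.9
  pres <- data.frame(x = c(5000, 6000, 5500, 6500),
                     y = c(4500, 5000, 5500, 4800),
                     year = c(1960, 1960, 1965, 1968))
  fx$mega_patch <- list(hsm = hsm, theta = theta, block = block,
                        presences = pres)

  # -- archipelago: 20 cone blobs (r = 0.5 km) at graded distances in a
  #    permeable matrix (cost contrast kept gentle: hard cost cliffs are
  #    near-impermeable to the movement model)
  i <- 1:19
  blobs <- data.frame(
    x_km = c(10, 10 + (1.8 + 0.38 * i) * cos(i * 2.39996)),
    y_km = c(10, 10 + (1.8 + 0.38 * i) * sin(i * 2.39996)),
    radius_km = 0.5, value = 0.85, edge_value = 0.58,
    skirt_km = 0.8, skirt_value = 0.55)
  spec <- synth_spec(c(20, 20), suit_mean = 0.5, suit_sd = 0.03,
                     background_cap = 0.55, blobs = blobs, seed = seed + 2L)
  hsm <- generate_hsm(spec)
  fx$archipelago <- list(hsm = hsm, theta = theta, blobs = blobs,
                         seed_blob = 1L, origin = c(10000, 10000))

  # -- uniform_matrix: constant sub-threshold surface
  spec <- synth_spec(c(5, 5), suit_mean = 0.3, suit_sd = 0,
                     seed = seed + 3L)
  fx$uniform_matrix <- list(hsm = generate_hsm(spec), theta = theta)

  fx
}
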