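#' Construct a suitability raster
#'
#' A `suit_raster` is the package's basic spatial container: a rectangular
#' grid of values on a projected coordinate system, stored as a base matrix
#' with row 1 the northernmost row. Nodata cells are `NA`.
#'
#' @param values Numeric matrix; row 1 = northernmost row. `NA` = nodata.
#' @param cell_size Cell edge length in metres (> 0).
#' @param xll,yll Projected coordinates (metres) of the lower-left corner
#'   of the grid (corner registration, as in the ESRI ASCII dialect).
#' @param crs_tag Opaque identifier for the coordinate reference system;
#'   carried through but never interpreted.
#' @param expected_range Optional length-2 numeric; every non-`NA` value must
#'   fall inside `[expected_range[1], expected_range[2]]`.
#' @return An object of class `suit_raster`.
#' @export
suit_raster <- function(values, cell_size, xll = 0, yll = 0, crs_tag = NA_character_,
                        expected_range = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (!is.null(expected_range)) {
    bad <- which(!is.na(values) &
                   (values < expected_range[1] | values > expected_range[2]))
    if (length(bad)) {
      rc <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(values))
      stop(sprintf(
        "%d cell(s) outside expected range [%g, %g]; first offenders (row, col): %s",
        length(bad), expected_range[1], expected_range[2],
        paste(apply(rc, 1, function(z) sprintf("(%d,%d)", z[1], z[2])), collapse = " ")),
        call. = FALSE)
    }
  }
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 crs_tag = crs_tag),
            class = "suit_raster")
}

#' @export
print.suit_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<suit_raster> %d rows x %d cols @ %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.suit_raster <- function(x) dim(x$values)

# x/y coordinates of every cell centre, in raster storage order
# (column-major over the matrix). Returned as an n x 2 matrix.
cell_centres <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), nc)
  cbind(x = r$xll + (col - 0.5) * r$cell_size,
        y = r$yll + (nr - row + 0.5) * r$cell_size)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$xll, b$xll)) && isTRUE(all.equal(a$yll, b$yll))
}

#' Read a single-band ESRI ASCII grid
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' dialect. Values equal to the declared nodata sentinel become `NA`.
#' GeoTIFF input is not supported in this build; rasters must be supplied
#' as ASCII grids on a common 100 m-class grid.
#'
#' @param path Path to an `.asc` file.
#' @param expected_range Optional `[lo, hi]` validation interval.
#' @return A [suit_raster].
#' @export
read_ascii_raster <- function(path, expected_range = NULL) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # file rows run N -> S
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  suit_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
              expected_range = expected_range)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r A [suit_raster].
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits for formatting (values are written with
#'   `format(..., digits)`); integers round-trip exactly.
#' @export
write_ascii_raster <- function(r, path, nodata = -9999, digits = 15) {
  v <- r$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row)
    paste(format(row, trim = TRUE, digits = digits, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# round-half-away-from-zero; base round() uses banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Scale a suitability raster to integers 0-100
#'
#' Multiplies by 100 and rounds to integers (half away from zero), the
#' format consumed by patch-based simulation tools. Nodata is preserved.
#'
#' @param hsm A [suit_raster] with values in `[0, 1]`.
#' @return A `suit_raster` whose values are integers in 0..100.
#' @export
scale_suitability <- function(hsm) {
  v <- hsm$values
  bad <- which(!is.na(v) & (v < 0 | v > 1))
  if (length(bad)) stop("suitability values outside [0, 1]", call. = FALSE)
  out <- hsm
  out$values <- round_half_up(v * 100)
  out
}

#' Invert a scaled habitat raster into a movement-cost surface
#'
#' Cost is `100 - scaled value`, floored at `cost_floor` so fully suitable
#' cells keep a strictly positive cost (inverse-cost step weights stay
#' finite). Nodata cells remain nodata: they are off-map for movement.
#'
#' @param scaled A `suit_raster` with integer values 0..100.
#' @param cost_floor Minimum cost (default 1).
#' @return A `suit_raster` of positive costs.
#' @export
invert_to_cost <- function(scaled, cost_floor = 1) {
  v <- scaled$values
  if (any(!is.na(v) & (v < 0 | v > 100)))
    stop("scaled values must lie in 0..100", call. = FALSE)
  out <- scaled
  out$values <- pmax(100 - v, cost_floor)
  out
}

#' Build a regular square evaluation grid (fishnet)
#'
#' Cells are anchored at `(x0, y0)` and ceil-cover the requested extent, so
#' a partial row/column at the far edge is included. Used both for the
#' 10 x 10 km evaluation grid and for the 1 km blocks of the Grid
#' delineation method.
#'
#' @param xmin,ymin,xmax,ymax Extent in metres.
#' @param cell_size Cell edge in metres (> 0).
#' @param x0,y0 Anchor for the grid origin; defaults to the extent corner.
#' @return An object of class `fishnet` with fields `nx`, `ny`, `cell_size`,
#'   `x0`, `y0`. Cell ids run 1..nx*ny, row-major from the south-west corner.
#' @export
make_fishnet <- function(xmin, ymin, xmax, ymax, cell_size,
                         x0 = xmin, y0 = ymin) {
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (xmax <= xmin || ymax <= ymin) stop("degenerate extent", call. = FALSE)
  nx <- ceiling((xmax - x0) / cell_size - 1e-9)
  ny <- ceiling((ymax - y0) / cell_size - 1e-9)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_size = cell_size, x0 = x0, y0 = y0),
            class = "fishnet")
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cell_size, x$x0, x$y0))
  invisible(x)
}

#' Fishnet cell id containing each point
#'
#' Points on a shared cell boundary belong to the cell to the north-east
#' (half-open cells `[x0 + i*cs, x0 + (i+1)*cs)`), so every point maps to
#' exactly one cell.
#'
#' @param fn A [make_fishnet] grid.
#' @param xy Two-column matrix of point coordinates (metres).
#' @return Integer cell ids; `NA` for points outside the grid.
#' @export
fishnet_cell_of <- function(fn, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  ix <- floor((xy[, 1] - fn$x0) / fn$cell_size)
  iy <- floor((xy[, 2] - fn$y0) / fn$cell_size)
  ok <- ix >= 0 & ix < fn$nx & iy >= 0 & iy < fn$ny
  id <- ifelse(ok, iy * fn$nx + ix + 1, NA_integer_)
  as.integer(id)
}

# rectangle [xmin,xmax] x [ymin,ymax] of a fishnet cell id
fishnet_cell_rect <- function(fn, id) {
  id0 <- id - 1L
  ix <- id0 %% fn$nx
  iy <- id0 %/% fn$nx
  cbind(xmin = fn$x0 + ix * fn$cell_size,
        ymin = fn$y0 + iy * fn$cell_size,
        xmax = fn$x0 + (ix + 1) * fn$cell_size,
        ymax = fn$y0 + (iy + 1) * fn$cell_size)
}

#' Total number of cells in a fishnet
#' @param fn A fishnet.
#' @return Integer count.
#' @export
fishnet_n_cells <- function(fn) fn$nx * fn$ny
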