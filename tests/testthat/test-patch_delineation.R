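test_that("threshold_mask is inclusive at the threshold and false on nodata", {
  r <- suit_raster(matrix(c(0.56, 0.559, NA, 0.9), 2, 2), 100)
  m <- threshold_mask(r, 0.56)
  expect_identical(m, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  all_na <- suit_raster(matrix(NA_real_, 3, 3), 100)
  expect_false(any(threshold_mask(all_na, 0.56)))
  expect_error(threshold_mask(r, 0), "theta")
})

test_that("8-connectivity labelling handles the worked examples", {
  mask <- matrix(as.logical(c(1,1,0,0, 0,1,0,1, 0,0,0,1, 1,0,0,1)),
                 4, 4, byrow = TRUE)
  lab <- label_contiguous(mask)
  sizes <- sort(tabulate(lab[lab > 0]))
  expect_equal(sizes, c(1, 3, 3))
  expect_equal(max(label_contiguous(matrix(TRUE, 3, 3))), 1)
  # checkerboard: diagonal adjacency links everything
  cb <- matrix((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2 == 0, 6, 6)
  expect_equal(max(label_contiguous(cb)), 1)
})

test_that("labelling matches the flood-fill oracle on random masks", {
  set.seed(101)
  for (i in 1:200) {
    mask <- matrix(runif(400) < runif(1, 0.2, 0.7), 20, 20)
    expect_identical(label_contiguous(mask), oracle_label(mask))
  }
})

test_that("filter_by_area uses a strict lower bound and re-indexes", {
  # two components: 5 cells and 6 cells; cell area 0.01 km^2, min 0.06
  mask <- matrix(FALSE, 3, 10)
  mask[1, 1:5] <- TRUE
  mask[3, 4:9] <- TRUE
  lab <- label_contiguous(mask)
  out <- filter_by_area(lab, 0.06, 0.01)
  expect_equal(sort(unique(out[out > 0])), 1L)       # survivor re-indexed to 1
  expect_equal(sum(out > 0), 6)                      # 0.06 >= 0.06 kept
  expect_identical(filter_by_area(lab, 0, 0.01), lab)  # min 0 -> identity
})

test_that("size classification follows the home-range bounds", {
  expect_equal(classify_patch_size(c(0.03, 0.06, 1.0, 1.2)),
               c("small", "medium", "medium", "large"))
  expect_error(classify_patch_size(-1), "non-negative")
})

test_that("balanced points honour density, spacing and the weight bias", {
  r <- make_uniform_raster(50, 50, 0.8)   # 25 km^2
  mask <- matrix(TRUE, 50, 50)
  bp <- sample_balanced_points(r, mask, density = 1, min_distance = 150,
                               seed = 5)
  expect_equal(nrow(bp$points), 25)
  d <- as.matrix(dist(bp$points))
  expect_true(all(d[upper.tri(d)] >= 150))
  # all points inside the masked extent
  expect_true(all(bp$points >= 0 & bp$points <= 5000))

  # two-level raster: weight 0.9 west half, 0.3 east half -> 3:1 point mass
  v <- cbind(matrix(0.9, 60, 60), matrix(0.3, 60, 60))
  r2 <- suit_raster(v, 100, 0, 0)
  bp2 <- sample_balanced_points(r2, matrix(TRUE, 60, 120), min_distance = 0,
                                seed = 9, n = 600)
  frac_west <- mean(bp2$points[, 1] < 6000)
  se <- sqrt(0.75 * 0.25 / 600)
  expect_lt(abs(frac_west - 0.75), 4 * se)

  # single-cell mask: the point falls within that cell
  mask1 <- matrix(FALSE, 50, 50); mask1[10, 20] <- TRUE
  bp1 <- sample_balanced_points(r, mask1, seed = 2, n = 1)
  expect_equal(nrow(bp1$points), 1)
  expect_true(bp1$points[1, 1] > 1900 && bp1$points[1, 1] < 2000)
  expect_true(bp1$points[1, 2] > 4000 && bp1$points[1, 2] < 4100)
  expect_error(sample_balanced_points(r, matrix(FALSE, 50, 50)), "empty")
})

test_that("voronoi assignment equals exhaustive nearest-point search", {
  r <- make_uniform_raster(50, 50, 0.5)
  mask <- matrix(TRUE, 50, 50)
  centres <- patchspread:::cell_centres(r)
  set.seed(11)
  for (i in 1:10) {
    pts <- cbind(runif(10, 0, 5000), runif(10, 0, 5000))
    lab <- voronoi_assign(pts, mask, r)
    expected <- matrix(0L, 50, 50)
    expected[mask] <- oracle_nearest(pts, centres[which(mask), ])
    expect_identical(lab, expected)
  }
  # two points on a strip: split at the perpendicular bisector
  strip <- make_uniform_raster(1, 10, 0.5)
  lab <- voronoi_assign(rbind(c(150, 50), c(850, 50)), matrix(TRUE, 1, 10), strip)
  expect_equal(as.integer(lab), rep(c(1L, 2L), each = 5))
  # one point: everything is patch 1
  expect_true(all(voronoi_assign(rbind(c(500, 50)), matrix(TRUE, 1, 10), strip) == 1))
  expect_error(voronoi_assign(matrix(numeric(0), ncol = 2),
                              matrix(TRUE, 1, 10), strip), "point")
})

test_that("grid delineation averages blocks and drops sub-threshold means", {
  # 2 km x 1 km toy raster: west block mean 0.6, east block mean 0.5
  v <- cbind(matrix(0.6, 10, 10), matrix(0.5, 10, 10))
  v[1, 11] <- 0.598  # east mean stays below theta
  r <- suit_raster(v, 100, 0, 0)
  pl <- delineate_grid(r, 0.56)
  expect_equal(nrow(pl$table), 1)
  expect_equal(pl$table$mean_suit, 0.6)
  expect_equal(pl$table$n_cells, 100)
  expect_true(all(pl$patch_raster[, 11:20] == 0))
  expect_error(delineate_grid(r, 0.56, grid_cell_m = 150), "multiple")
})

test_that("contiguity delineation counts blobs and areas correctly", {
  v <- matrix(0.2, 10, 10)
  v[2, 2:5] <- 0.8; v[3, 3:5] <- 0.8          # 7-cell blob
  v[8, 8] <- 0.9                               # too small, removed
  r <- suit_raster(v, 100, 0, 0)
  pl <- delineate_contiguity(r, 0.56)
  expect_equal(nrow(pl$table), 1)
  expect_equal(pl$table$area_km2, 0.07)
  # two blobs separated by a >= 1 cell gap stay distinct
  v2 <- matrix(0.2, 10, 10)
  v2[2:4, 2:4] <- 0.9
  v2[2:4, 7:9] <- 0.9
  expect_equal(nrow(delineate_contiguity(suit_raster(v2, 100), 0.56)$table), 2)
  # empty mask -> valid empty landscape
  empty <- delineate_contiguity(make_uniform_raster(5, 5, 0.3), 0.56)
  expect_equal(nrow(empty$table), 0)
  expect_true(all(empty$patch_raster == 0))
})

test_that("voronoi delineation keeps only patches meeting the threshold", {
  hi <- make_uniform_raster(40, 40, 0.9)   # 16 km^2
  pl <- delineate_voronoi(hi, 0.56, seed = 3)
  expect_gt(nrow(pl$table), 0)
  expect_true(all(pl$table$mean_suit >= 0.56))
  lo <- make_uniform_raster(40, 40, 0.3)
  expect_equal(nrow(delineate_voronoi(lo, 0.56, seed = 3)$table), 0)
})

test_that("vorcon passes medium patches through and partitions large ones", {
  # medium blobs only: identical to contiguity output
  v <- matrix(0.2, 20, 20)
  v[3:5, 3:6] <- 0.8       # 12 cells = 0.12 km^2, medium
  v[12:15, 12:15] <- 0.7   # 16 cells, medium
  r <- suit_raster(v, 100, 0, 0)
  plc <- delineate_contiguity(r, 0.56)
  plv <- delineate_vorcon(r, 0.56, seed = 4)
  expect_identical(plv$patch_raster, plc$patch_raster)
  expect_equal(plv$table$area_km2, plc$table$area_km2)

  # one 9 km^2 uniform blob: ~9 sub-patches partitioning the parent exactly
  v2 <- matrix(0.2, 40, 40)
  v2[6:35, 6:35] <- 0.9
  r2 <- suit_raster(v2, 100, 0, 0)
  plv2 <- delineate_vorcon(r2, 0.56, seed = 8)
  expect_gte(nrow(plv2$table), 2)
  expect_equal(sum(plv2$table$n_cells), 900)
  parent <- v2 >= 0.56
  expect_identical(plv2$patch_raster > 0, parent)
  # all parent cells >= theta, so every sub-patch mean >= theta
  expect_true(all(plv2$table$mean_suit >= 0.56))
})

test_that("raising theta never increases retained patch area", {
  spec <- synth_spec(c(4, 4), suit_mean = 0.45, suit_sd = 0.15,
                     autocorr_m = 300, seed = 21)
  hsm <- generate_hsm(spec)
  for (method in c("grid", "voronoi", "contiguity", "vorcon")) {
    areas <- vapply(c(0.4, 0.5, 0.6, 0.7), function(th)
      sum(delineate(hsm, method, th, seed = 33)$table$area_km2), numeric(1))
    expect_true(all(diff(areas) <= 1e-9), info = method)
  }
})

test_that("patch export writes the paired rasters and table", {
  v <- matrix(0.2, 10, 10); v[2:4, 2:5] <- 0.8
  pl <- delineate_contiguity(suit_raster(v, 100), 0.56)
  dir <- withr::local_tempdir()
  paths <- export_patch_landscape(pl, dir)
  expect_true(all(file.exists(paths)))
  idr <- read_ascii_raster(paths[1])
  qr <- read_ascii_raster(paths[2])
  expect_equal(max(idr$values), 1)
  expect_equal(max(qr$values), 80)    # mean suit 0.8 scaled
  tab <- read.csv(paths[3])
  expect_equal(tab$n_cells, 12)
})
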