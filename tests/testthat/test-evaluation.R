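test_that("minimum convex polygon equals the gift-wrapping oracle", {
  tri <- rbind(c(0, 0), c(4, 0), c(2, 3))
  expect_equal(nrow(minimum_convex_polygon(tri)), 3)
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1))
  hull <- minimum_convex_polygon(sq)
  expect_equal(nrow(hull), 4)                 # interior point absorbed
  set.seed(17)
  for (i in 1:20) {
    pts <- cbind(runif(100), runif(100))
    h <- minimum_convex_polygon(pts)
    expect_equal(hull_vertex_set(h), hull_vertex_set(oracle_hull(pts)),
                 ignore_attr = TRUE)
  }
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1))), "3")
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "collinear")
})

test_that("observed ranges are cumulative and fall back when degenerate", {
  fn <- make_fishnet(0, 0, 40000, 40000, 10000)
  # presences forming a 15 x 15 km square within cells (0,0)-(1,1)
  sq <- data.frame(x = c(1000, 16000, 16000, 1000),
                   y = c(1000, 1000, 16000, 16000), year = 1965)
  later <- data.frame(x = 35000, y = 35000, year = 1985)
  obs <- observed_ranges(rbind(sq, later), c(1969, 1989), fn)
  expect_equal(length(obs[[1]]$obs_range), 4)     # 2 x 2 cells intersected
  expect_true(all(obs[[1]]$obs_range %in% obs[[2]]$obs_range))
  expect_gt(length(obs[[2]]$obs_range), 4)
  expect_true(all(obs[[1]]$obs_presences %in% obs[[1]]$obs_range))
  # degenerate first period: falls back to presence cells with a warning
  lin <- data.frame(x = c(5000, 15000, 25000), y = rep(5000, 3), year = 1960)
  expect_warning(obs2 <- observed_ranges(lin, c(1961), fn), "degenerate")
  expect_equal(length(obs2[[1]]$obs_range), 3)
  # empty timestep flagged and skipped (the second, single-point period also
  # warns about degenerate geometry)
  w <- capture_warnings(obs3 <- observed_ranges(later, c(1960, 1989), fn))
  expect_match(w, "skipped", all = FALSE)
  expect_true(obs3[[1]]$empty)
})

test_that("simulated range cells match a brute-force scan", {
  v <- matrix(0.2, 40, 40)                     # 4 x 4 km, 1 km fishnet
  v[18:22, 18:22] <- 0.9                       # patch spans a cell boundary
  pl <- delineate_contiguity(suit_raster(v, 100), 0.56)
  fn <- make_fishnet(0, 0, 4000, 4000, 1000)
  cells <- simulated_range_cells(1L, pl, fn)
  # oracle: scan every patch cell centre
  centres <- patchspread:::cell_centres(suit_raster(pl$patch_raster, 100))
  expected <- sort(unique(fishnet_cell_of(fn,
    centres[which(pl$patch_raster == 1), ])))
  expect_equal(cells, expected)
  expect_gt(length(cells), 1)
  expect_equal(simulated_range_cells(integer(0), pl, fn), integer(0))
})

test_that("TSS follows the standard definitions", {
  region <- 1:10
  expect_equal(true_skill_statistic(1:4, 1:4, region)$tss, 1)
  r <- true_skill_statistic(region, 1:4, region)   # predict everything
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0)
  expect_equal(r$tss, 0)
  # hand-counted table: TP=3, FN=1, FP=2, TN=4
  r2 <- true_skill_statistic(predicted = c(1, 2, 3, 5, 6),
                             observed = c(1, 2, 3, 4), region = 1:10)
  expect_equal(r2[, c("TP", "FP", "FN", "TN")],
               data.frame(TP = 3, FP = 2, FN = 1, TN = 4))
  expect_equal(r2$sensitivity, 0.75)
  expect_equal(r2$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(round(r2$tss, 4), 0.4167)
  # undefined components reported as missing
  expect_true(is.na(true_skill_statistic(1:3, integer(0), 1:10)$sensitivity))
})

test_that("random predictions at fixed prevalence have TSS near zero", {
  set.seed(23)
  region <- 1:200
  observed <- 1:60
  tss <- replicate(1000, {
    true_skill_statistic(sample(region, 60), observed, region)$tss
  })
  expect_lt(abs(mean(tss)), 0.05)
})

test_that("evaluate_timeseries reduces per-timestep TSS correctly", {
  fx <- fixtures(1)
  hsm <- fx$archipelago$hsm
  pl <- delineate_contiguity(hsm, 0.56)
  cost <- invert_to_cost(scale_suitability(hsm))
  fn <- make_fishnet(0, 0, 20000, 20000, 2000)
  seed_id <- pl$patch_raster[100, 100]
  cfg <- sim_config(replicates = 4, total_years = 60, seed = 5,
                    n_report_timesteps = 3)
  occ <- run_simulation(pl, cost, seed_id, cfg)
  # observations constructed to equal the simulated range at each timestep:
  # perfect prediction gives TSS 1 whenever both classes are present
  obs <- lapply(1:3, function(t) {
    cells <- simulated_range_cells(which(occ$occupied[t, ]), pl, fn)
    list(end_year = t, empty = FALSE, mcp = NULL,
         obs_range = cells, obs_presences = cells)
  })
  class(obs) <- "range_observation"
  ev <- evaluate_timeseries(occ, pl, obs, fn)
  ok <- is.finite(ev$per_timestep$tss)
  expect_true(all(ev$per_timestep$tss[ok] == 1))
  # double-entry: tss column equals sens + spec - 1 recomputed from counts
  pt <- ev$per_timestep[is.finite(ev$per_timestep$tss), ]
  expect_gt(nrow(pt), 0)
  expect_equal(pt$tss, pt$TP / (pt$TP + pt$FN) + pt$TN / (pt$TN + pt$FP) - 1)
  # summary equals hand-computed stats over the defined timesteps
  sub <- pt[pt$comparator == "obs_range" & is.finite(pt$tss), ]
  summ <- ev$summary[ev$summary$comparator == "obs_range", ]
  expect_equal(summ$n_used, nrow(sub))
  expect_gt(summ$n_used, 0)
  expect_equal(summ$mean, mean(sub$tss))
  expect_equal(summ$sd, sd(sub$tss))
  expect_equal(c(summ$min, summ$max), range(sub$tss))
  expect_error(evaluate_timeseries(occ, pl, obs[1:2], fn), "differ")
})

test_that("maxSSS threshold scans candidates with the tie rule", {
  expect_equal(maxsss_threshold(c(0.9, 0.8, 0.6), c(0.5, 0.4, 0.2, 0.1)), 0.6)
  same <- c(0.3, 0.5, 0.7)
  expect_equal(maxsss_threshold(same, same), 0.3)   # ties -> smallest
  expect_equal(maxsss_threshold(c(0.8, 0.9), c(0.1, 0.2)), 0.8)
  expect_error(maxsss_threshold(numeric(0), 1), "non-empty")
})

test_that("jaccard similarity behaves on edge cases", {
  expect_equal(jaccard(1:4, 1:4), 1)
  expect_equal(jaccard(1:2, 3:4), 0)
  expect_equal(jaccard(1:3, 2:4), 0.5)
  expect_equal(jaccard(integer(0), integer(0)), 1)
})
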