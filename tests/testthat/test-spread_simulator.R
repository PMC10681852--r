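# small helper: environment for an arbitrary suitability matrix
env_from_values <- function(v, config = sim_config(), theta = 0.56) {
  hsm <- suit_raster(v, 100, 0, 0)
  pl <- delineate_contiguity(hsm, theta)
  cost <- invert_to_cost(scale_suitability(hsm))
  list(pl = pl, cost = cost, env = make_sim_env(pl, cost, config))
}

test_that("density dependence follows the exponential decay", {
  expect_equal(density_dependent_rate(1, 1, 0), 1)
  expect_equal(density_dependent_rate(1, 1, 1), 0.36788, tolerance = 1e-4)
  expect_equal(density_dependent_rate(1, 1, 3), 0.04979, tolerance = 1e-4)
  expect_equal(density_dependent_rate(1, 0, 5), 1)   # b = 0: no decay
})

test_that("carrying capacity is linear in area x suitability with a floor", {
  expect_equal(patch_carrying_capacity(1.0, 1.0, 1), 1)
  expect_equal(patch_carrying_capacity(1.5, 0.8, 10), 12)
  expect_equal(patch_carrying_capacity(0.06, 0.56, 1), 1)
})

test_that("settlement probability steps down around carrying capacity", {
  expect_equal(settlement_probability(0.5, 1), 1, tolerance = 1e-15)
  expect_equal(settlement_probability(1, 1), 0.5)
  expect_equal(settlement_probability(1.5, 1), 0, tolerance = 1e-15)
})

test_that("effective cost is the inverse-distance-weighted ray mean", {
  # uniform surface: any direction returns the constant
  unif <- suit_raster(matrix(20, 11, 11), 100)
  for (d in 1:8) expect_equal(effective_cost(unif, 6, 6, d, 4), 20)
  # hand-computed ray: costs 10, 20, 30, 40 eastward
  v <- matrix(50, 5, 9)
  v[3, 5:8] <- c(10, 20, 30, 40)
  r <- suit_raster(v, 100)
  expected <- sum(c(10, 20, 30, 40) / (1:4)) / sum(1 / (1:4))
  expect_equal(effective_cost(r, 3, 4, 3, 4), expected)
  expect_equal(round(expected, 1), 19.2)
  # facing off-map: disallowed
  expect_equal(effective_cost(r, 3, 9, 3, 4), Inf)
})

test_that("step weights combine persistence and inverse cost", {
  unif <- suit_raster(matrix(20, 21, 21), 100)
  cfg <- sim_config()
  w0 <- step_weights(unif, 11, 11, 0, cfg)
  expect_equal(w0, rep(1 / 8, 8))
  # heading east: straight/reverse ratio = DP
  w <- step_weights(unif, 11, 11, 3, cfg)
  expect_equal(w[3] / w[7], 5)
  expect_equal(w[2] / w[3], 5^(3 / 4) / 5)   # 45 deg off
  # DP = 1: proportional to inverse effective cost only
  v <- matrix(20, 21, 21); v[, 1:10] <- 40
  r <- suit_raster(v, 100)
  cfg1 <- sim_config(directional_persistence = 1)
  w1 <- step_weights(r, 11, 11, 3, cfg1)
  expect_equal(w1[3] / w1[7], effective_cost(r, 11, 11, 7, 4) /
                 effective_cost(r, 11, 11, 3, 4))
})

test_that("reproduction matches its closed-form mean", {
  cfg <- sim_config()
  expect_equal(reproduce(0L, 0, cfg), 0L)    # no adults, no offspring
  set.seed(500)
  draws <- replicate(10000, reproduce(1L, 1, cfg))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exp(-1)), 3 * se)
  # b = 0: mean equals fecundity x adults
  cfg0 <- sim_config(dd_b = 0)
  set.seed(501)
  draws0 <- replicate(5000, reproduce(5L, 5, cfg0))
  expect_lt(abs(mean(draws0) - 5), 3 * sd(draws0) / sqrt(5000))
})

test_that("the step budget bounds Euclidean displacement at 20 km", {
  # 1-row free corridor, natal patch at the west end, near-deterministic
  # straight walk: the cardinal path attains the bound exactly
  v <- matrix(0.5, 1, 250)
  v[1, 1:3] <- 0.9
  hsm <- suit_raster(v, 100, 0, 0)
  pl <- delineate_contiguity(hsm, 0.56, size_class_bounds(small_max = 0.0001))
  cost <- invert_to_cost(scale_suitability(hsm))
  cfg <- sim_config(directional_persistence = 1e9)
  env <- make_sim_env(pl, cost, cfg)
  expect_equal(max_dispersal_distance(cfg, 100), 20000)
  set.seed(77)
  disp <- replicate(20, transfer(env, 1, start_cell = 1, config = cfg)$displacement_m)
  expect_lte(max(disp), 20000)
  expect_equal(max(disp), 20000)   # straight path realises the bound
})

test_that("dispersers cross the corridor fixture and settle in B", {
  fx <- fixtures(1)
  e <- env_from_values(fx$two_patch_corridor$hsm$values)
  set.seed(11)
  outcomes <- replicate(1000, transfer(e$env, 1)$outcome)
  expect_gt(mean(outcomes == 2), 0.95)
  # B above capacity: settlement collapses and dispersers die
  set.seed(12)
  n_over <- c(0, 1.5 * e$env$K[2])
  out2 <- replicate(200, transfer(e$env, 1, N = n_over)$outcome)
  expect_true(all(out2 == 0))
})

test_that("a year conserves individuals and an isolated patch persists", {
  v <- matrix(0.2, 10, 10); v[4:6, 4:6] <- 0.9
  e <- env_from_values(v)
  cfg <- sim_config()
  set.seed(3)
  st <- init_state(e$env, 1L, 100)
  for (y in 1:100) st <- simulate_year(st, e$env, cfg)
  expect_true(all(patchspread:::state_adults(st) > 0))   # never extinct
  expect_equal(st$log$emigrated, st$log$settled + st$log$died)
  # empty landscape stays empty
  st0 <- init_state(e$env, 1L, 5)
  st0$cohorts[] <- 0
  for (y in 1:5) st0 <- simulate_year(st0, e$env, cfg)
  expect_equal(sum(patchspread:::state_adults(st0)), 0)
})

test_that("run_simulation is deterministic and applies the 0.7 threshold", {
  fx <- fixtures(1)
  e <- env_from_values(fx$two_patch_corridor$hsm$values)
  cfg <- sim_config(replicates = 10, total_years = 20, seed = 99)
  occ1 <- run_simulation(e$pl, e$cost, 1L, cfg)
  occ2 <- run_simulation(e$pl, e$cost, 1L, cfg)
  expect_identical(occ1$occupancy, occ2$occupancy)
  expect_identical(occ1$mean_occupancy, occ2$mean_occupancy)
  # threshold semantics: 0.7 occupied, 0.6 not
  expect_true(all((occ1$mean_occupancy >= 0.7) == occ1$occupied))
  expect_error(run_simulation(e$pl, e$cost, 99L, cfg), "subset")
})

test_that("initialisation selects patches by buffer and by cells", {
  v <- matrix(0.2, 30, 200)   # 20 km x 3 km
  v[14:16, 10:14] <- 0.9      # patch near x = 1-1.5 km
  v[14:16, 180:190] <- 0.9    # patch near x = 18-19 km
  hsm <- suit_raster(v, 100, 0, 0)
  pl <- delineate_contiguity(hsm, 0.56)
  pres <- data.frame(x = c(1000, 1400), y = c(1500, 1700), year = 1960)
  ids <- init_from_buffer(pl, pres, radius = 10000)
  expect_equal(ids, 1L)                        # far patch ~17 km away excluded
  expect_equal(sort(init_from_buffer(pl, pres, radius = 19000)), c(1L, 2L))
  expect_error(init_from_buffer(pl, data.frame(x = 5000, y = 1500, year = 1),
                                radius = 100), "cannot start")
  fn <- make_fishnet(0, 0, 20000, 3000, 10000)
  expect_equal(init_from_cells(pl, pres, fn), 1L)
  pres2 <- rbind(pres, data.frame(x = 18500, y = 1500, year = 1970))
  expect_equal(sort(init_from_cells(pl, pres2, fn)), c(1L, 2L))
})
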