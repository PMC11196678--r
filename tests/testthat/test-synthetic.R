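test_that("environment layers honour trends, seasons and determinism", {
  g <- grid_spec(4)
  # no trend, no noise: identical months across years
  env0 <- generate_environment(quiet_scenario(0), g, 1)
  expect_identical(env_layer(env0, "sst", 2015, 7), env_layer(env0, "sst", 2077, 7))
  # linear warming: 2100 minus 2015 global mean equals rate * 8.5 decades
  envw <- generate_environment(quiet_scenario(0.3), g, 1)
  d <- annual_mean(envw, "sst", 2100) - annual_mean(envw, "sst", 2015)
  expect_equal(mean(d, na.rm = TRUE), 0.3 * 8.5, tolerance = 1e-10)
  # same seed, bit-identical noisy layers; different seed differs
  sc <- default_scenarios()[[2]]
  e1 <- generate_environment(sc, g, 9)
  e2 <- generate_environment(sc, g, 9)
  e3 <- generate_environment(sc, g, 10)
  expect_identical(env_layer(e1, "sst", 2050, 3), env_layer(e2, "sst", 2050, 3))
  expect_false(identical(env_layer(e1, "sst", 2050, 3),
                         env_layer(e3, "sst", 2050, 3)))
  # static layers ignore time
  expect_identical(env_layer(e1, "depth"), env_layer(e1, "depth", 2100, 12))
})

test_that("warmer scenarios end the century warmer (noise-free ordering)", {
  g <- grid_spec(4)
  rates <- c(0.18, 0.30, 0.45)
  means <- vapply(rates, function(r) {
    env <- generate_environment(quiet_scenario(r), g, 1)
    mean(annual_mean(env, "sst", 2100), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("sea ice shrinks and stays poleward of the retreating edge", {
  g <- grid_spec(2)
  sc <- default_scenarios()[["SSP-like-5-8.5"]]
  env <- generate_environment(sc, g, 3)
  i15 <- env_layer(env, "ice_cover", 2015, 3, noise = FALSE)
  i00 <- env_layer(env, "ice_cover", 2100, 3, noise = FALSE)
  expect_true(all(i00 <= i15 + 1e-9, na.rm = TRUE))
  expect_true(sum(i00, na.rm = TRUE) < sum(i15, na.rm = TRUE))
  lat <- lat_field(g)
  expect_true(all(abs(lat[!is.na(i15) & i15 > 0]) > 55))
})

test_that("true suitability matches the Gaussian product formula", {
  env <- test_env()
  sp <- virtual_species("spX", "brown_macroalgae",
                        list(sst = c(12, 4), salinity = c(34, 5)))
  s <- true_suitability(sp, env, 2020)
  sst <- annual_mean(env, "sst", 2020)
  sal <- annual_mean(env, "salinity", 2020)
  manual <- exp(-(sst - 12)^2 / (2 * 16)) * exp(-(sal - 34)^2 / (2 * 25))
  expect_equal(s, manual)
  expect_error(true_suitability(
    virtual_species("bad", "seagrasses", list(phantom = c(0, 1))), env, 2020),
    "absent")
})

test_that("occupancy limits: impossible niches are empty, infinite breadth fills the coast", {
  env <- test_env()
  cold <- virtual_species("cold", "brown_macroalgae", list(sst = c(-80, 1)))
  expect_equal(sum(true_occupancy(cold, env, 2015)), 0)
  broad <- virtual_species("broad", "brown_macroalgae",
                           list(sst = c(10, 1e9), salinity = c(35, 1e9)))
  expect_equal(true_occupancy(broad, env, 2015), env$light_valid)
})

test_that("warming contracts a cold-adapted species' true range", {
  g <- grid_spec(2)
  env <- generate_environment(quiet_scenario(0.45), g, 5)
  sst_lv <- annual_mean(env, "sst", 2015)[env$light_valid]
  cold_opt <- stats::quantile(sst_lv, 0.1, names = FALSE)
  sp <- virtual_species("cold", "brown_macroalgae", list(sst = c(cold_opt, 3)))
  expect_lte(sum(true_occupancy(sp, env, 2100)), sum(true_occupancy(sp, env, 2015)))
})

test_that("occurrence sampling respects support, count and uniformity", {
  env <- test_env()
  sps <- generate_species(3, env, 7)
  sp <- sps[[1]]
  recs <- sample_occurrences(sp, env, 10, bias_strength = 0.5, seed = 2)
  expect_equal(nrow(recs), 10)
  # all records fall inside the true occupied support of the window
  occ <- Reduce(`|`, lapply(2015:2020, function(y) true_occupancy(sp, env, y)))
  idx <- cell_index(env$grid, recs$longitude, recs$latitude)
  expect_true(all(occ[idx]))
  # determinism
  expect_identical(recs, sample_occurrences(sp, env, 10, bias_strength = 0.5, seed = 2))
  # unbiased sampling is multinomial-uniform over occupied cells
  n_occ <- sum(occ)
  big <- sample_occurrences(sp, env, 60 * n_occ, bias_strength = 0, seed = 3)
  counts <- tabulate(match(cell_index(env$grid, big$longitude, big$latitude),
                           which(occ)), nbins = n_occ)
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})
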