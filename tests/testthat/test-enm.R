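small_presence <- function(env, seed = 13, n = 120) {
  sp <- generate_species(2, env, seed)[[1]]
  recs <- sample_occurrences(sp, env, n, seed = seed)
  rasterize_presence(recs, env$grid, env$light_valid)
}

test_that("pseudo-absences are equal-size, disjoint and reproducible", {
  env <- test_env()
  pg <- small_presence(env)
  n_pres <- sum(pg$presence)
  ab <- sample_pseudo_absences(pg, env$light_valid, seed = 3)
  expect_length(ab, n_pres)
  expect_length(intersect(ab, which(pg$presence)), 0)
  expect_true(all(env$light_valid[ab]))
  expect_identical(ab, sample_pseudo_absences(pg, env$light_valid, seed = 3))
  expect_false(identical(ab, sample_pseudo_absences(pg, env$light_valid, seed = 4)))
  # explicit n is honoured
  expect_length(sample_pseudo_absences(pg, env$light_valid, n = 40, seed = 1), 40)
  # asking for more than the candidate pool names both counts
  expect_error(sample_pseudo_absences(pg, env$light_valid, n = 1e6, seed = 1),
               "1e\\+06|1000000")
})

test_that("feature tables have one column per variable-month plus statics", {
  env <- test_env()
  cells <- which(env$light_valid)[1:25]
  x <- build_feature_table(cells, env, 2015:2020)
  expect_equal(ncol(x), 5 * 12 + 2)  # 5 dynamic variables x 12 months + 2 static
  expect_equal(nrow(x), 25)
  expect_true(all(c("sst_m01", "ice_cover_m12", "depth", "shortwave") %in% names(x)))
  # a variable with no trend/noise/season contributes 12 equal monthly features
  qenv <- generate_environment(quiet_scenario(0), env$grid, 1)
  xq <- build_feature_table(cells, qenv, 2015:2020, dynamic_vars = "salinity")
  sal <- as.matrix(xq[, sprintf("salinity_m%02d", 1:12)])
  expect_equal(apply(sal, 1, function(r) max(r) - min(r)), rep(0, 25))
  # cells with missing layers (land) are dropped by the training assembler
  land <- which(!env$ocean)[1]
  pg <- small_presence(env)
  expect_message(tt <- training_table(pg, c(land), env, 2015:2020), "dropped")
  expect_equal(nrow(tt$x), sum(pg$presence))
})

test_that("elimination keeps the planted driver and near-optimal accuracy", {
  set.seed(7)
  n <- 400
  x <- as.data.frame(matrix(rnorm(n * 20), n, 20,
                            dimnames = list(NULL, sprintf("f%02d", 1:20))))
  y <- factor(as.integer(x$f07 + rnorm(n, 0, 0.3) > 0), levels = c(0, 1))
  m <- fit_with_elimination(x, y, drop_per_iter = 5, num_trees = 200, seed = 1)
  expect_true("f07" %in% m$selected_features)
  full_oob <- m$oob_trace$oob[1]
  expect_gte(m$oob_score, full_oob - 0.02)
  expect_equal(m$oob_trace$n_features, c(20, 15, 10, 5))
  # same table and seed select identical features
  m2 <- fit_with_elimination(x, y, drop_per_iter = 5, num_trees = 200, seed = 1)
  expect_identical(m2$selected_features, m$selected_features)
  expect_equal(m2$oob_score, m$oob_score)
})

test_that("refitting with a different seed barely moves the OOB score", {
  env <- test_env()
  pg <- small_presence(env, seed = 23, n = 150)
  ab <- sample_pseudo_absences(pg, env$light_valid, seed = 7)
  tt <- training_table(pg, ab, env, 2015:2020)
  o <- vapply(1:2, function(s)
    fit_with_elimination(tt$x, tt$y, num_trees = 300, seed = s)$oob_score, 0)
  expect_lt(abs(diff(o)), 0.05)
})

test_that("no elimination happens when the drop exceeds the feature count", {
  set.seed(8)
  x <- as.data.frame(matrix(rnorm(600), 100, 6,
                            dimnames = list(NULL, sprintf("f%d", 1:6))))
  y <- factor(as.integer(x$f1 > 0), levels = c(0, 1))
  m <- fit_with_elimination(x, y, drop_per_iter = 10, num_trees = 100, seed = 2)
  expect_equal(nrow(m$oob_trace), 1)
  expect_setequal(m$selected_features, names(x))
  expect_error(fit_with_elimination(x, factor(rep(1, 100), levels = c(0, 1))),
               "single class")
})

test_that("projection is self-consistent and masks invalid cells", {
  env <- test_env()
  pg <- small_presence(env, seed = 19)
  ab <- sample_pseudo_absences(pg, env$light_valid, seed = 5)
  tt <- training_table(pg, ab, env, 2015:2020)
  m <- fit_with_elimination(tt$x, tt$y, num_trees = 150, seed = 6,
                            label = pg$label)
  expect_true(all(m$oob_trace$oob >= 0 & m$oob_trace$oob <= 1))
  # predicting on the training features reproduces the fitted probabilities
  direct <- predict(m$forest, data = tt$x[, m$selected_features],
                    num.threads = 1)$predictions[, "1"]
  cells <- tt$cells
  sm <- project_suitability(m, env, 2020, cells = cells)
  # the projector uses single-year features, so compare through the same path
  x2020 <- build_feature_table(cells, env, 2020)
  via_predict <- predict(m$forest, data = x2020[, m$selected_features],
                         num.threads = 1)$predictions[, "1"]
  expect_equal(sm$p[cells], via_predict)
  expect_true(all(sm$p >= 0 & sm$p <= 1, na.rm = TRUE))
  expect_true(all(is.na(sm$p[!env$ocean])))
  # all-masked input cells give an all-masked map
  land_cells <- which(!env$ocean)[1:5]
  sm_land <- project_suitability(m, env, 2020, cells = land_cells)
  expect_true(all(is.na(sm_land$p)))
  expect_length(direct, length(cells))
})

test_that("suitability tracks the planted niche and warming direction", {
  env <- memo("env_warm", {
    generate_environment(default_scenarios()[["SSP-like-5-8.5"]], grid_spec(2), 42)
  })
  sst_lv <- annual_mean(env, "sst", 2015)[env$light_valid]
  sp <- virtual_species("cold1", "brown_macroalgae",
                        list(sst = c(stats::quantile(sst_lv, 0.25, names = FALSE), 3.5)))
  recs <- sample_occurrences(sp, env, 250, seed = 9)
  pg <- rasterize_presence(recs, env$grid, env$light_valid)
  ab <- sample_pseudo_absences(pg, env$light_valid, seed = 9)
  tt <- training_table(pg, ab, env, 2015:2020)
  m <- fit_with_elimination(tt$x, tt$y, num_trees = 300, seed = 9, label = "cold1")
  cells <- which(env$light_valid)
  p15 <- project_suitability(m, env, 2015, cells = cells)$p
  p00 <- project_suitability(m, env, 2100, cells = cells)$p
  # niche monotonicity: mean p near the optimum beats mean p far from it
  sst15 <- annual_mean(env, "sst", 2015)
  near <- env$light_valid & abs(sst15 - sp$niche$sst[1]) <= sp$niche$sst[2]
  far <- env$light_valid & abs(sst15 - sp$niche$sst[1]) > 3 * sp$niche$sst[2]
  expect_gt(mean(p15[near], na.rm = TRUE), mean(p15[far], na.rm = TRUE))
  # warming pushes the species out of cells that exit its thermal niche:
  # suitable at calibration, beyond 2 niche-sd by end of century
  sst00 <- annual_mean(env, "sst", 2100)
  exit <- env$light_valid &
    abs(sst15 - sp$niche$sst[1]) <= sp$niche$sst[2] &
    (sst00 - sp$niche$sst[1]) > 2 * sp$niche$sst[2]
  expect_gt(sum(exit), 5)
  a <- cell_area(env$grid)
  wmean <- function(p) sum(p[exit] * a[exit], na.rm = TRUE) /
    sum(a[exit][!is.na(p[exit])])
  expect_lt(wmean(p00), wmean(p15))
})
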