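# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, expr, .fixtures)
  get(key, .fixtures)
}

# a 2-degree world under the intermediate scenario, no pipeline attached
test_env <- function() memo("env", {
  generate_environment(default_scenarios()[["SSP-like-3-7.0"]], grid_spec(2), 42)
})

# noise-free twin (for closed-form checks)
quiet_scenario <- function(warming_rate = 0, years = 2015:2100) {
  scenario_params("quiet", warming_rate = warming_rate, ice_retreat_rate = 0,
                  salinity_trend = 0, productivity_trend = 0,
                  noise_sd = c(sst = 0, air_temp = 0, salinity = 0,
                               productivity = 0, ice_cover = 0),
                  years = years)
}

# the full recovery run used by the acceptance-style checks: one warm
# scenario, 12 virtual species, fixed seed
recovery_run <- function() memo("recovery", {
  cfg <- default_config(seed = 42)
  cfg$scenarios <- default_scenarios()["SSP-like-5-8.5"]
  cfg$n_species <- 12
  dir <- file.path(tempdir(), "macrocast-recovery")
  res <- suppressWarnings(run_pipeline(cfg, outdir = dir, quiet = TRUE))
  res$outdir <- dir
  res
})

# a fast end-to-end configuration: coarse grid, short horizon, few trees
smoke_config <- function(seed = 3) {
  cfg <- default_config(seed)
  cfg$grid <- grid_spec(4)
  sc <- default_scenarios()[["SSP-like-5-8.5"]]
  sc$years <- 2015:2035
  cfg$scenarios <- list(`SSP-like-5-8.5` = sc)
  cfg$years <- 2015:2035
  cfg$n_species <- 5
  cfg$rf$num_trees <- 100
  cfg
}

smoke_run <- function() memo("smoke", {
  dir <- file.path(tempdir(), "macrocast-smoke")
  res <- suppressWarnings(run_pipeline(smoke_config(), outdir = dir, quiet = TRUE))
  res$outdir <- dir
  res
})

# ground-truth richness under the no-dispersal assumption (occupancy in
# year y intersected with first-year occupancy), per group
true_richness_no_dispersal <- function(res, group, year) {
  env <- res$envs[[1]]
  y0 <- res$config$years[1]
  ids <- vapply(res$species, function(s) s$species_id, "")
  grp <- vapply(res$species, function(s) s$group, "")
  members <- which(ids %in% res$eoo_summary$species_id & grp == group)
  Reduce(`+`, lapply(members, function(i) {
    o <- true_occupancy(res$species[[i]], env, year) &
      true_occupancy(res$species[[i]], env, y0)
    o * 1L
  }))
}
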