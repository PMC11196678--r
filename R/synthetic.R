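# Virtual world generator: scenario-driven environmental layers, virtual
# species with known Gaussian niches, and spatially biased occurrence samples.
# Everything downstream of this module can be validated against the ground
# truth it plants.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded stages do not perturb each other.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a master seed
#'
#' Fans one master seed out to per-stage child seeds (environment, species,
#' sampling, model fits) so stages can be re-run independently yet
#' reproducibly. Stays below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param ... integer stage keys
#' @return integer child seed
#' @export
child_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) s <- (s * 7919 + as.double(k)) %% 2147483647
  as.integer(s)
}

#' Emissions-scenario parameters for the synthetic world
#'
#' Scenario knobs loosely patterned on the Shared Socio-economic Pathway
#' family: a linear sea-surface/air warming trend, polar sea-ice retreat,
#' weak regional salinity and productivity trends, a latitude-scaled
#' seasonal cycle and per-variable observation noise.
#'
#' @param label scenario name
#' @param warming_rate degC per decade added to sst and air_temp (uniform
#'   in space, so global means drift linearly)
#' @param ice_retreat_rate percent of ice cover lost per decade (also moves
#'   the ice edge poleward at `ice_retreat_rate/4` degrees per decade)
#' @param salinity_trend PSU per decade at the equator, reversing sign
#'   toward the poles (regional structure)
#' @param productivity_trend g m^-3 day^-1 per decade, scaled by latitude
#' @param seasonal_amplitude degC seasonal sst half-range at the poles
#' @param noise_sd named vector of per-variable noise standard deviations
#' @param years projection years (default 2015:2100)
#' @return object of class `scenario_params`
#' @export
scenario_params <- function(label,
                            warming_rate,
                            ice_retreat_rate,
                            salinity_trend = -0.05,
                            productivity_trend = 0.01,
                            seasonal_amplitude = 5,
                            noise_sd = c(sst = 0.3, air_temp = 0.5,
                                         salinity = 0.2, productivity = 0.05,
                                         ice_cover = 2),
                            years = 2015:2100) {
  stopifnot(warming_rate >= 0, all(diff(years) == 1))
  structure(list(label = label, warming_rate = warming_rate,
                 ice_retreat_rate = ice_retreat_rate,
                 salinity_trend = salinity_trend,
                 productivity_trend = productivity_trend,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd, years = years),
            class = "scenario_params")
}

#' The three default emissions scenarios
#'
#' Warming rates (0.18, 0.30, 0.45 degC/decade) bracket the range of
#' end-of-century sea-surface warming under moderate-to-high emissions
#' pathways; ice retreat scales with warming.
#'
#' @return named list of three [scenario_params()]
#' @export
default_scenarios <- function() {
  list(
    `SSP-like-2-4.5` = scenario_params("SSP-like-2-4.5", warming_rate = 0.18,
                                       ice_retreat_rate = 5),
    `SSP-like-3-7.0` = scenario_params("SSP-like-3-7.0", warming_rate = 0.30,
                                       ice_retreat_rate = 8),
    `SSP-like-5-8.5` = scenario_params("SSP-like-5-8.5", warming_rate = 0.45,
                                       ice_retreat_rate = 12)
  )
}

# deterministic geography: continent potential from Gaussian blobs with
# longitude wraparound; land where the potential exceeds 0.55
.continent_potential <- function(lat, lon) {
  blobs <- rbind(
    c(1.00,  55, -100, 18, 35),
    c(1.00,  20,   25, 25, 30),
    c(0.95,  60,   90, 15, 40),
    c(0.90, -25,  135, 18, 25),
    c(0.90, -40,  -65, 15, 18),
    c(1.00, -80,    0, 12, 100),
    c(0.80,  78,  -40,  8, 60))
  C <- 0
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    dlon <- ((lon - b[3] + 180) %% 360) - 180
    C <- C + b[1] * exp(-((lat - b[2])^2 / (2 * b[4]^2) + dlon^2 / (2 * b[5]^2)))
  }
  C
}

.dynamic_vars <- c("sst", "air_temp", "salinity", "productivity", "ice_cover")
.static_vars <- c("depth", "shortwave", "light_bottom")

#' Generate the synthetic environment for one scenario
#'
#' Builds the world's static geography (continents from fixed Gaussian
#' blobs; depth increasing away from the coast; yearly seabed irradiance
#' decaying exponentially with depth so a contiguous coastal band passes
#' the 50 E m^-2 yr^-1 photosynthesis threshold; static incoming shortwave
#' radiation) and returns a lazy layer provider: monthly dynamic fields
#' (sst, air_temp, salinity, productivity, ice_cover) are evaluated on
#' demand by [env_layer()] from closed-form latitudinal baselines plus the
#' scenario's trends, seasonal cycle and seeded noise, so an 86-year
#' monthly archive never has to be materialized.
#'
#' @param scenario a [scenario_params()]
#' @param grid a [grid_spec()]
#' @param seed integer seed controlling the noise fields
#' @return object of class `synthetic_env` with precomputed static layers
#'   (`depth`, `shortwave`, `light_bottom`), the `ocean` and `light_valid`
#'   masks, and everything [env_layer()] needs
#' @export
generate_environment <- function(scenario, grid, seed) {
  stopifnot(inherits(scenario, "scenario_params"), inherits(grid, "grid_spec"))
  LAT <- lat_field(grid); LON <- lon_field(grid)
  C <- .continent_potential(LAT, LON)
  ocean <- C < 0.55
  t_off <- pmax(0.55 - C, 0) / 0.55        # 0 at the coast, 1 far offshore
  depth <- pmax(6000 * t_off^3, 3)
  depth[!ocean] <- NA
  L0 <- 9000 * pmax(cos(LAT * pi / 180), 0.15)
  light <- L0 * exp(-depth / 25)
  light[!ocean] <- NA
  shortwave <- 170 + 180 * cos(LAT * pi / 180)
  shortwave[!ocean] <- NA
  env <- structure(list(scenario = scenario, grid = grid, seed = seed,
                        ocean = ocean, lat = LAT, lon = LON,
                        static = list(depth = depth, shortwave = shortwave,
                                      light_bottom = light)),
                   class = "synthetic_env")
  env$light_valid <- light_mask(raster_layer(grid, light, "light_bottom",
                                             "E m-2 yr-1"))
  env
}

# noise-free deterministic component of a dynamic monthly field
.env_deterministic <- function(env, var, year, month) {
  sc <- env$scenario
  LAT <- env$lat
  phi <- LAT * pi / 180
  dec <- (year - sc$years[1]) / 10
  peak <- ifelse(LAT >= 0, 8, 2)    # warmest month per hemisphere
  seas <- cos(2 * pi * (month - peak) / 12)
  v <- switch(var,
    sst = 28.5 * pmax(cos(phi), 0)^1.7 - 1.5 +
      sc$seasonal_amplitude * sqrt(abs(LAT) / 90) * seas +
      sc$warming_rate * dec,
    air_temp = 40 * pmax(cos(phi), 0)^1.4 - 12 +
      1.6 * sc$seasonal_amplitude * sqrt(abs(LAT) / 90) * seas +
      sc$warming_rate * dec,
    salinity = 34 + 2.2 * exp(-((abs(LAT) - 25) / 15)^2) -
      1.2 * exp(-((abs(LAT) - 65) / 18)^2) +
      sc$salinity_trend * dec * cos(LAT * pi / 90),
    productivity = {
      p <- 0.15 + 0.6 * (abs(LAT) / 90) + 0.4 * exp(-env$static$depth / 300) +
        sc$productivity_trend * dec * (abs(LAT) / 90 - 0.3)
      pmax(p, 0.01)
    },
    ice_cover = {
      edge <- 62 + (sc$ice_retreat_rate / 4) * dec - 3 * seas
      cover <- 100 * pmin(pmax((abs(LAT) - edge) / 6, 0), 1)
      cover * pmax(1 - sc$ice_retreat_rate / 100 * dec, 0)
    },
    stop("unknown dynamic variable: ", var))
  v
}

#' Evaluate one environmental layer of the synthetic world
#'
#' Static variables (`depth`, `shortwave`, `light_bottom`) ignore the time
#' arguments (mirroring the constant-radiation and constant-bathymetry
#' assumption of the projection setup). Dynamic variables are the
#' deterministic scenario component plus, when `noise = TRUE` and the
#' scenario's `noise_sd` is positive, an i.i.d. Gaussian field seeded
#' deterministically from `(seed, variable, year, month)` — two calls with
#' the same coordinates are bit-identical.
#'
#' @param env a [generate_environment()] result
#' @param var variable name
#' @param year,month time coordinates (required for dynamic variables)
#' @param noise include the seeded noise field? Ground-truth computations
#'   use `noise = FALSE`
#' @return matrix on the environment's grid (`NA` on land)
#' @export
env_layer <- function(env, var, year = NULL, month = NULL, noise = TRUE) {
  if (var %in% .static_vars) return(env$static[[var]])
  if (!var %in% .dynamic_vars) stop("unknown variable: ", var)
  stopifnot(!is.null(year), !is.null(month))
  v <- .env_deterministic(env, var, year, month)
  sd <- env$scenario$noise_sd[var]
  if (noise && !is.na(sd) && sd > 0) {
    vi <- match(var, .dynamic_vars)
    s <- child_seed(env$seed, 11L, vi, year, month)
    v <- v + with_seed(s, matrix(stats::rnorm(length(v), 0, sd),
                                 nrow(v), ncol(v)))
  }
  if (var == "ice_cover") v <- pmin(pmax(v, 0), 100)
  if (var == "productivity") v <- pmax(v, 0)
  v[!env$ocean] <- NA
  v
}

#' Annual mean of a variable (12-month average)
#'
#' @param env a `synthetic_env`
#' @param var variable name
#' @param year year
#' @param noise include noise fields (default `FALSE`: the ground-truth
#'   deterministic climate)
#' @return matrix on the environment's grid
#' @export
annual_mean <- function(env, var, year, noise = FALSE) {
  if (var %in% .static_vars) return(env$static[[var]])
  acc <- 0
  for (m in 1:12) acc <- acc + env_layer(env, var, year, m, noise = noise)
  acc / 12
}

# ---- virtual species ---------------------------------------------------------

#' Create a virtual species with a known Gaussian niche
#'
#' True suitability is the product over niche variables of
#' `exp(-(x - mu)^2 / (2 sigma^2))`, evaluated on noise-free annual-mean
#' layers; true occupancy is deterministic: suitability at or above
#' `prevalence_threshold` on light-valid cells. Keeping the truth
#' noise-free separates process from observation error, which enters only
#' through occurrence sampling.
#'
#' @param species_id identifier
#' @param group `"brown_macroalgae"` or `"seagrasses"`
#' @param niche named list; each element `c(mu, sigma)` for one variable
#' @param prevalence_threshold suitability cutoff defining occupancy
#' @param detectability probability an occupied cell yields a record (used
#'   by the dataset-level sampler to draw record counts)
#' @return object of class `virtual_species`
#' @export
virtual_species <- function(species_id, group, niche,
                            prevalence_threshold = 0.3, detectability = 0.9) {
  stopifnot(all(vapply(niche, function(n) n[2] > 0, TRUE)))
  structure(list(species_id = species_id, group = group, niche = niche,
                 prevalence_threshold = prevalence_threshold,
                 detectability = detectability),
            class = "virtual_species")
}

#' True suitability raster of a virtual species
#'
#' Direct evaluation of the Gaussian product response on the noise-free
#' annual-mean environment of `year`.
#'
#' @param sp a [virtual_species()]
#' @param env a `synthetic_env`
#' @param year year
#' @return matrix of suitabilities in (0, 1], `NA` on land
#' @export
true_suitability <- function(sp, env, year) {
  s <- 1
  for (v in names(sp$niche)) {
    if (!(v %in% c(.dynamic_vars, .static_vars)))
      stop("niche variable absent from environment: ", v)
    x <- annual_mean(env, v, year, noise = FALSE)
    mu <- sp$niche[[v]][1]; sig <- sp$niche[[v]][2]
    s <- s * exp(-(x - mu)^2 / (2 * sig^2))
  }
  s
}

#' True occupancy raster of a virtual species
#'
#' @inheritParams true_suitability
#' @return logical matrix: suitability >= prevalence threshold on
#'   light-valid cells
#' @export
true_occupancy <- function(sp, env, year) {
  s <- true_suitability(sp, env, year)
  occ <- !is.na(s) & s >= sp$prevalence_threshold & env$light_valid
  occ
}

#' Sample a community of virtual species
#'
#' Niche optima for sst are drawn between the 5% and 70% quantiles of the
#' present-day annual-mean sst over light-valid cells (so warming erodes
#' the warm edge of most ranges); salinity and light optima are centred on
#' the values of a random light-valid cell with broad breadths, keeping
#' sst the dominant niche axis. Species failing to occupy at least
#' `min_occupied` cells at the first year are redrawn (up to 50 tries).
#' Roughly one species in five is labelled a seagrass, the rest brown
#' macroalgae, mirroring the two analysis groups.
#'
#' @param n_species number of species
#' @param env a `synthetic_env`
#' @param seed integer seed
#' @param params sampler settings; see Details in the source. Defaults:
#'   sst sigma in (2.5, 5) degC, salinity sigma in (3, 6) PSU, light sigma
#'   in (2000, 6000) E m^-2 yr^-1, prevalence threshold 0.3,
#'   detectability 0.9, min_occupied 20
#' @return list of [virtual_species()]
#' @export
generate_species <- function(n_species, env, seed,
                             params = list()) {
  p <- utils::modifyList(list(
    vars = c("sst", "salinity", "light_bottom"),
    sst_q = c(0.05, 0.70), sst_sigma = c(2.5, 5),
    sal_sigma = c(3, 6), light_sigma = c(2000, 6000),
    prevalence_threshold = 0.3, detectability = 0.9,
    min_occupied = 20), params)
  year0 <- env$scenario$years[1]
  lv <- env$light_valid
  sst0 <- annual_mean(env, "sst", year0)[lv]
  sal0 <- annual_mean(env, "salinity", year0)[lv]
  li0 <- env$static$light_bottom[lv]
  sst_rng <- stats::quantile(sst0, p$sst_q, names = FALSE)
  with_seed(child_seed(seed, 23L), {
    species <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      for (try in 1:50) {
        anchor <- sample.int(length(sst0), 1)
        niche <- list(
          sst = c(stats::runif(1, sst_rng[1], sst_rng[2]),
                  stats::runif(1, p$sst_sigma[1], p$sst_sigma[2])),
          salinity = c(sal0[anchor], stats::runif(1, p$sal_sigma[1], p$sal_sigma[2])),
          light_bottom = c(li0[anchor],
                           stats::runif(1, p$light_sigma[1], p$light_sigma[2])))
        niche <- niche[p$vars]
        sp <- virtual_species(sprintf("sp%03d", i),
                              if (i %% 5 == 0) "seagrasses" else "brown_macroalgae",
                              niche,
                              prevalence_threshold = p$prevalence_threshold,
                              detectability = p$detectability)
        if (sum(true_occupancy(sp, env, year0)) >= p$min_occupied) break
        sp <- NULL
      }
      if (is.null(sp))
        stop("could not draw a species with >= ", p$min_occupied, " occupied cells")
      species[[i]] <- sp
    }
    species
  })
}

#' Sample biased occurrence records for one species
#'
#' Records are drawn only from cells occupied during the sampling window
#' (union of yearly true-occupancy rasters). Sampling effort interpolates
#' between uniform over occupied cells (`bias_strength = 0`) and clustered
#' around `n_hotspots` effort hotspots (`bias_strength = 1`), emulating
#' the geographic clustering of real survey effort; the record point is
#' placed uniformly inside the chosen cell.
#'
#' @param sp a [virtual_species()]
#' @param env a `synthetic_env`
#' @param n_records number of records to draw (exactly this many returned)
#' @param bias_strength in `[0, 1]`
#' @param seed integer seed
#' @param years sampling window (default the first six scenario years)
#' @param n_hotspots number of effort hotspots
#' @return data.frame with `species_id`, `longitude`, `latitude`, `year`
#' @export
sample_occurrences <- function(sp, env, n_records, bias_strength = 0.5, seed = 1,
                               years = NULL, n_hotspots = 3) {
  stopifnot(n_records >= 1, bias_strength >= 0, bias_strength <= 1)
  if (is.null(years)) years <- env$scenario$years[1:6]
  occ <- Reduce(`|`, lapply(years, function(y) true_occupancy(sp, env, y)))
  cells <- which(occ)
  if (!length(cells)) stop("species ", sp$species_id, " occupies no cells in the window")
  g <- env$grid
  row <- (cells - 1L) %% g$n_rows + 1L
  col <- (cells - 1L) %/% g$n_rows + 1L
  res <- g$resolution_deg
  clat <- g$lat_min + (row - 0.5) * res
  clon <- g$lon_min + (col - 0.5) * res
  with_seed(child_seed(seed, 31L), {
    w <- rep(1, length(cells))
    if (bias_strength > 0 && length(cells) > 1) {
      hot <- sample.int(length(cells), min(n_hotspots, length(cells)))
      r <- 10  # hotspot radius, degrees
      prox <- rep(0, length(cells))
      for (h in hot) {
        d2 <- (clat - clat[h])^2 + (pmin(abs(clon - clon[h]), 360 - abs(clon - clon[h])))^2
        prox <- pmax(prox, exp(-d2 / (2 * r^2)))
      }
      w <- (1 - bias_strength) + bias_strength * prox
    }
    pick <- sample.int(length(cells), n_records, replace = TRUE, prob = w)
    data.frame(species_id = sp$species_id,
               longitude = clon[pick] - res / 2 + stats::runif(n_records) * res,
               latitude = clat[pick] - res / 2 + stats::runif(n_records) * res,
               year = sample(years, n_records, replace = TRUE))
  })
}

#' Sample the full occurrence dataset for a community
#'
#' Per-species record counts are drawn from a negative binomial whose mean
#' is `n_mean` scaled by the species' detectability (so imperfect
#' detection thins effort), floored at 1; some species therefore fall
#' under the downstream 10-record filter, as in real datasets.
#'
#' @param species list of [virtual_species()]
#' @param env a `synthetic_env`
#' @param seed integer seed
#' @param n_mean mean records per species before detectability thinning
#' @param n_size negative-binomial size (dispersion) parameter
#' @param bias_strength spatial sampling bias passed to [sample_occurrences()]
#' @return data.frame of all records
#' @export
generate_occurrence_dataset <- function(species, env, seed, n_mean = 150,
                                        n_size = 2, bias_strength = 0.5) {
  counts <- with_seed(child_seed(seed, 37L), {
    mu <- n_mean * vapply(species, function(s) s$detectability, 1)
    pmax(stats::rnbinom(length(species), mu = mu, size = n_size), 1)
  })
  recs <- lapply(seq_along(species), function(i)
    sample_occurrences(species[[i]], env, counts[i],
                       bias_strength = bias_strength,
                       seed = child_seed(seed, 41L, i)))
  do.call(rbind, recs)
}
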