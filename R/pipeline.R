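# End-to-end orchestration: a single declarative config drives
# simulate -> occurrences -> eoo -> fit -> project -> diversity / habitat /
# aoo -> report. Every stochastic stage draws a child seed from the config
# seed, so a rerun with the same config reproduces every output.

#' Default pipeline configuration
#'
#' The reduced-scale virtual world the pipeline runs on by default: a
#' 2-degree global grid, 10 virtual species, the three default emissions
#' scenarios, yearly projections 2015-2100, a 2015-2020 calibration
#' window, 300-tree forests dropping 10 features per elimination step, and
#' the standard analysis thresholds. The full-resolution global setting of
#' the study system (0.5 degrees, hundreds of species, 500-tree forests)
#' is configuration, not code: raise `grid`, `n_species` and
#' `rf$num_trees` to scale up.
#'
#' @param seed master seed for every stochastic stage
#' @return named list understood by [run_pipeline()]
#' @export
default_config <- function(seed = 1) {
  list(
    grid = grid_spec(2),
    scenarios = default_scenarios(),
    n_species = 10,
    species_params = list(),
    sampling = list(n_mean = 150, n_size = 2, bias_strength = 0.5),
    calibration_years = 2015:2020,
    years = 2015:2100,
    dynamic_vars = c("sst", "air_temp", "salinity", "productivity", "ice_cover"),
    static_vars = c("depth", "shortwave"),
    rf = list(num_trees = 300, drop_per_iter = 10),
    eoo = list(alpha0 = 0.001, step = 0.005, ratio_threshold = 10,
               min_records = 10, fine_factor = 10),
    thresholds = c(0.6, 0.7, 0.8, 0.9),
    region_threshold = 0.6,
    epsilon = 1e-6,
    seed = seed)
}

#' Ground-truth species richness of the virtual world
#'
#' The number of species truly occupying each cell (sum of boolean
#' occupancies from the planted niches) — the recovery target for the
#' stacked-richness estimate.
#'
#' @param species list of [virtual_species()]
#' @param env a `synthetic_env`
#' @param year year
#' @return integer richness matrix
#' @export
true_richness <- function(species, env, year) {
  Reduce(`+`, lapply(species, function(sp) true_occupancy(sp, env, year) * 1L))
}

# project every model over all years: features are built per year but each
# model predicts once on the stacked (cells x years) table, which keeps the
# per-call prediction overhead negligible
.project_all <- function(models, env, years, cells, dynamic_vars, static_vars) {
  nc <- length(cells)
  x1 <- as.matrix(build_feature_table(cells, env, years[1],
                                      dynamic_vars = dynamic_vars,
                                      static_vars = static_vars))
  X <- matrix(NA_real_, nc * length(years), ncol(x1),
              dimnames = list(NULL, colnames(x1)))
  X[seq_len(nc), ] <- x1
  for (j in seq_along(years)[-1]) {
    X[(j - 1L) * nc + seq_len(nc), ] <-
      as.matrix(build_feature_table(cells, env, years[j],
                                    dynamic_vars = dynamic_vars,
                                    static_vars = static_vars))
  }
  ok <- stats::complete.cases(X)
  Xok <- X[ok, , drop = FALSE]  # extra columns are fine: ranger picks by name
  out <- lapply(models, function(m) {
    pred <- rep(NA_real_, nrow(X))
    pred[ok] <- stats::predict(m$forest, data = Xok,
                               num.threads = 1)$predictions[, "1"]
    matrix(pred, nc, length(years), dimnames = list(NULL, years))
  })
  names(out) <- vapply(models, function(m) m$label, "")
  out
}

# yearly mean/SE of per-cell log-e percentage change relative to the first
# column, on a cells x years richness matrix (vectorized twin of
# mean_local_change_trajectory)
.trajectory_from_cells <- function(R, years, epsilon) {
  base <- R[, 1]
  m <- s <- numeric(length(years))
  for (j in seq_along(years)) {
    ok <- !is.na(base) & !is.na(R[, j]) & base > epsilon & R[, j] > epsilon
    v <- 100 * (log(R[ok, j]) - log(base[ok]))
    m[j] <- mean(v)
    s[j] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  out <- data.frame(year = years, mean = m, se = s, row.names = NULL)
  attr(out, "binned") <- bin_trajectory(years, m, s)
  out
}

.log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full forecasting pipeline
#'
#' Executes every stage in dependency order on the synthetic world defined
#' by `config` and (optionally) persists tidy CSV outputs plus a JSON run
#' manifest to `outdir`. Stage structure and the persisted files are
#' described in the package vignette; every headline number in the summary
#' table is recomputable from the persisted intermediates with the
#' corresponding module function.
#'
#' @param config a [default_config()]-shaped list
#' @param outdir output directory (created if missing), or `NULL` to skip
#'   persistence
#' @param quiet suppress progress messages
#' @return (invisibly) a list with all in-memory stage results: `envs`,
#'   `species`, `records`, `presence`, `eoo`, and per scenario the fitted
#'   `models`, projected probabilities, richness maps, trajectories,
#'   habitat and area-of-occupancy tables, plus the `summary` data.frame
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  t0 <- Sys.time()
  grid <- config$grid
  areas <- cell_area(grid)
  seed <- config$seed
  years <- config$years
  cal <- config$calibration_years

  # ---- simulate -------------------------------------------------------------
  envs <- lapply(seq_along(config$scenarios), function(i)
    generate_environment(config$scenarios[[i]], grid, child_seed(seed, 1L, i)))
  names(envs) <- names(config$scenarios)
  light_valid <- envs[[1]]$light_valid
  .log_stage(quiet, "simulate: %d scenarios, %d light-valid of %d ocean cells",
             length(envs), sum(light_valid), sum(envs[[1]]$ocean))
  species <- generate_species(config$n_species, envs[[1]],
                              child_seed(seed, 2L), config$species_params)
  records <- generate_occurrence_dataset(species, envs[[1]],
                                         child_seed(seed, 3L),
                                         n_mean = config$sampling$n_mean,
                                         n_size = config$sampling$n_size,
                                         bias_strength = config$sampling$bias_strength)
  groups_of <- stats::setNames(vapply(species, function(s) s$group, ""),
                               vapply(species, function(s) s$species_id, ""))

  # ---- occurrences ----------------------------------------------------------
  filt <- filter_min_records(records, config$eoo$min_records)
  retained <- filt$retained$species_id
  .log_stage(quiet, "occurrences: %d records; %d of %d species retained (>= %d records)",
             nrow(records), length(retained), length(species),
             config$eoo$min_records)
  presence <- lapply(retained, function(id)
    rasterize_presence(filt$records[filt$records$species_id == id, ],
                       grid, light_valid, label = id))
  names(presence) <- retained
  group_names <- c("brown_macroalgae", "seagrasses")
  group_pres <- lapply(group_names, function(gname) {
    members <- retained[groups_of[retained] == gname]
    if (!length(members)) return(NULL)
    group_presence(presence[members], gname)
  })
  names(group_pres) <- group_names
  group_pres <- Filter(Negate(is.null), group_pres)

  # ---- eoo ------------------------------------------------------------------
  eoo <- lapply(retained, function(id) {
    xy <- as.matrix(filt$records[filt$records$species_id == id,
                                 c("longitude", "latitude")])
    hull <- fit_alpha(xy, alpha0 = config$eoo$alpha0, step = config$eoo$step,
                      ratio_threshold = config$eoo$ratio_threshold)
    rasterize_and_clip(hull, grid, light_valid, species_id = id,
                       fine_factor = config$eoo$fine_factor)
  })
  names(eoo) <- retained
  eoo_summary <- data.frame(
    species_id = retained,
    group = unname(groups_of[retained]),
    alpha_final = vapply(eoo, function(e) e$alpha_final, 0),
    n_cells = vapply(eoo, function(e) sum(e$mask), 0),
    eoo_km2 = vapply(eoo, function(e) sum(areas[e$mask]), 0))
  .log_stage(quiet, "eoo: hulls for %d species, median %d cells",
             length(eoo), as.integer(stats::median(eoo_summary$n_cells)))

  cells <- which(light_valid)
  regions <- region_mask(grid)
  yr0 <- as.character(years[1]); yrN <- as.character(years[length(years)])
  scen_results <- list()
  summary_rows <- list()

  for (si in seq_along(envs)) {
    env <- envs[[si]]
    scen <- names(envs)[si]

    # ---- fit ----------------------------------------------------------------
    fit_one <- function(pres, drop_per_iter, key) {
      # equal-size classes, saturating at the available candidate cells when
      # a group covers more than half the coastal domain (possible at desk
      # scale; classes then stay mildly unbalanced)
      n_abs <- min(sum(pres$presence), sum(light_valid & !pres$presence))
      abs_cells <- sample_pseudo_absences(pres, light_valid, n = n_abs,
                                          seed = child_seed(seed, 4L, si, key))
      tt <- training_table(pres, abs_cells, env, cal,
                           dynamic_vars = config$dynamic_vars,
                           static_vars = config$static_vars)
      fit_with_elimination(tt$x, tt$y, drop_per_iter = drop_per_iter,
                           num_trees = config$rf$num_trees,
                           seed = child_seed(seed, 5L, si, key),
                           label = pres$label)
    }
    sp_models <- lapply(seq_along(presence), function(k)
      fit_one(presence[[k]], config$rf$drop_per_iter, k))
    names(sp_models) <- retained
    grp_models <- lapply(seq_along(group_pres), function(k)
      fit_one(group_pres[[k]], .Machine$integer.max, 1000L + k))
    names(grp_models) <- names(group_pres)
    .log_stage(quiet, "%s: fitted %d species + %d group models (mean OOB %.3f)",
               scen, length(sp_models), length(grp_models),
               mean(vapply(sp_models, function(m) m$oob_score, 0)))

    # ---- project ------------------------------------------------------------
    proj <- .project_all(c(sp_models, grp_models), env, years, cells,
                         config$dynamic_vars, config$static_vars)
    .log_stage(quiet, "%s: projected %d models over %d years on %d cells",
               scen, length(proj), length(years), length(cells))

    as_map <- function(vec) {
      p <- matrix(NA_real_, grid$n_rows, grid$n_cols)
      p[cells] <- vec
      p
    }

    area_vec <- areas[cells]
    eoo_vec <- lapply(eoo, function(e) e$mask[cells])

    # ---- diversity (per group, stacked species AOO maps) --------------------
    diversity <- list(); div_rows <- list(); lat_rows <- list()
    for (gname in names(group_pres)) {
      members <- retained[groups_of[retained] == gname]
      # cells x years richness: sum of EOO-clipped occurrence probabilities
      R <- Reduce(`+`, lapply(members, function(id) {
        P <- proj[[id]]
        P[is.na(P)] <- 0
        P * eoo_vec[[id]]
      }))
      rich_first <- as_map(R[, yr0]); rich_first[is.na(rich_first)] <- 0
      rich_last <- as_map(R[, yrN]); rich_last[is.na(rich_last)] <- 0
      traj <- .trajectory_from_cells(R, years, config$epsilon)
      frac10 <- fraction_losing(rich_first, rich_last, 0.10)
      change <- log_pct_change(rich_last, rich_first, config$epsilon)
      lat <- latitudinal_profile(change, grid)
      diversity[[gname]] <- list(richness_first = rich_first,
                                 richness_last = rich_last,
                                 trajectory = traj, change_map = change,
                                 latitudinal = lat, fraction_losing_10 = frac10)
      div_rows[[gname]] <- cbind(group = gname, scenario = scen, traj)
      lat_rows[[gname]] <- cbind(group = gname, scenario = scen, lat)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        group = gname, scenario = scen,
        metric = c("mean_local_diversity_change_pct",
                   "fraction_localities_losing_ge10pct"),
        value = c(traj$mean[nrow(traj)], frac10))
    }

    # ---- habitat (group-level suitability maps) -----------------------------
    hab_rows <- list(); share_rows <- list()
    for (gname in names(grp_models)) {
      P <- proj[[gname]]
      for (th in config$thresholds) {
        a <- colSums(area_vec * (!is.na(P) & P >= th))
        names(a) <- colnames(P)
        hab_rows[[paste(gname, th)]] <- data.frame(
          group = gname, scenario = scen, threshold = th,
          year = years, area_km2 = as.numeric(a))
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          group = gname, scenario = scen,
          metric = sprintf("habitat_pct_change_p%.1f", th),
          value = pct_change_area(a[yrN], a[yr0]))
      }
      for (y in c(yr0, yrN)) {
        sh <- regional_shares(as_map(P[, y]), regions,
                              config$region_threshold, light_valid, areas)
        share_rows[[paste(gname, y)]] <- cbind(
          group = gname, scenario = scen, year = as.integer(y),
          sh$shares, global_km2 = sh$global_km2)
      }
      polar_share <- function(y) {
        df <- share_rows[[paste(gname, y)]]
        sum(df$share_pct[regions$legend$band == "polar"])
      }
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        group = gname, scenario = scen,
        metric = c("polar_share_pct_first", "polar_share_pct_last"),
        value = c(polar_share(yr0), polar_share(yrN)))
    }

    # ---- aoo ----------------------------------------------------------------
    aoo_mat <- matrix(NA_real_, length(retained), length(years),
                      dimnames = list(retained, years))
    exp_mat <- aoo_mat
    r2015 <- stats::setNames(numeric(length(retained)), retained)
    for (id in retained) {
      P <- proj[[id]]
      P[is.na(P)] <- 0
      a <- colSums(P * (eoo_vec[[id]] * area_vec))
      s <- colSums(P * area_vec)
      aoo_mat[id, ] <- a
      exp_mat[id, ] <- proportional_expansion(a[yr0], s[yr0], s)
      r2015[id] <- a[yr0] / s[yr0]
    }
    aoo_traj_rows <- list()
    for (gname in names(group_pres)) {
      members <- retained[groups_of[retained] == gname]
      traj <- mean_aoo_trajectory(aoo_mat[members, , drop = FALSE])
      traj_exp <- mean_aoo_trajectory(exp_mat[members, , drop = FALSE])
      for (what in c("km2", "pct")) {
        aoo_traj_rows[[paste(gname, what, "nd")]] <- cbind(
          group = gname, scenario = scen, hypothesis = "no_dispersal",
          statistic = what, traj[[what]])
        aoo_traj_rows[[paste(gname, what, "pe")]] <- cbind(
          group = gname, scenario = scen, hypothesis = "proportional_expansion",
          statistic = what, traj_exp[[what]])
      }
      n <- length(members)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        group = gname, scenario = scen,
        metric = c("mean_aoo_pct_change", "mean_aoo_expansion_pct_change"),
        value = c(traj$pct$mean[length(years)],
                  traj_exp$pct$mean[length(years)]))
    }
    aoo_series <- do.call(rbind, lapply(retained, function(id) data.frame(
      species_id = id, group = unname(groups_of[id]), scenario = scen,
      year = years, aoo_km2 = aoo_mat[id, ],
      aoo_expansion_km2 = exp_mat[id, ],
      R_2015 = unname(r2015[id]), row.names = NULL)))

    model_summary <- do.call(rbind, lapply(c(sp_models, grp_models), function(m)
      data.frame(scenario = scen, label = m$label,
                 n_features = length(m$selected_features),
                 oob = m$oob_score, row.names = NULL)))

    scen_results[[scen]] <- list(
      env = env, models = c(sp_models, grp_models), proj = proj, cells = cells,
      diversity = diversity,
      diversity_yearly = do.call(rbind, div_rows),
      latitudinal = do.call(rbind, lat_rows),
      habitat_area = do.call(rbind, hab_rows),
      regional_shares = do.call(rbind, share_rows),
      aoo = aoo_mat, aoo_expansion = exp_mat, aoo_series = aoo_series,
      model_summary = model_summary)
  }

  summary_df <- do.call(rbind, summary_rows)
  result <- list(config = config, envs = envs, species = species,
                 records = records, filter = filt, presence = presence,
                 group_presence = group_pres, eoo = eoo,
                 eoo_summary = eoo_summary, regions = regions,
                 areas = areas, light_valid = light_valid,
                 scenarios = scen_results, summary = summary_df)
  if (!is.null(outdir)) write_run_outputs(result, outdir)
  .log_stage(quiet, "pipeline complete in %.1f min",
             as.numeric(difftime(Sys.time(), t0, units = "mins")))
  invisible(result)
}

#' Persist pipeline outputs as tidy CSV plus a JSON manifest
#'
#' Writes the occurrence table, filter log, hull diagnostics, model
#' summaries, yearly and binned trajectories, habitat areas, regional
#' shares, per-species area-of-occupancy series, first/last-year richness
#' maps (text raster format) and the headline summary table; the manifest
#' records the package version, the full configuration and its hash, so
#' any headline number can be recomputed from the persisted intermediates.
#'
#' @param result a [run_pipeline()] result
#' @param outdir output directory
#' @return `outdir`, invisibly
#' @export
write_run_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(outdir, name),
                                           row.names = FALSE)
  w(result$records, "occurrences.csv")
  status_df <- function(df, s) cbind(df, status = rep(s, nrow(df)))
  w(rbind(status_df(result$filter$retained, "retained"),
          status_df(result$filter$dropped, "dropped")),
    "species_filter.csv")
  w(result$eoo_summary, "eoo_summary.csv")
  w(result$regions$legend, "region_legend.csv")
  bind_scen <- function(field) do.call(rbind, lapply(result$scenarios,
                                                     function(s) s[[field]]))
  w(bind_scen("model_summary"), "models.csv")
  w(bind_scen("diversity_yearly"), "diversity_yearly.csv")
  binned <- do.call(rbind, lapply(names(result$scenarios), function(scen) {
    s <- result$scenarios[[scen]]
    do.call(rbind, lapply(names(s$diversity), function(g)
      cbind(group = g, scenario = scen,
            attr(s$diversity[[g]]$trajectory, "binned"))))
  }))
  w(binned, "diversity_trajectory.csv")
  w(bind_scen("latitudinal"), "latitudinal_profile.csv")
  w(bind_scen("habitat_area"), "habitat_area.csv")
  w(bind_scen("regional_shares"), "regional_shares.csv")
  w(bind_scen("aoo_series"), "aoo_series.csv")
  w(result$summary, "summary.csv")
  yrs <- range(result$config$years)
  for (scen in names(result$scenarios)) {
    s <- result$scenarios[[scen]]
    for (g in names(s$diversity)) {
      for (which_y in c("first", "last")) {
        r <- s$diversity[[g]][[paste0("richness_", which_y)]]
        r[r == 0] <- NA  # persist sparsely; zero outside the stacked extents
        yr <- if (which_y == "first") yrs[1] else yrs[2]
        lay <- raster_layer(result$config$grid, r, "richness", "species",
                            year = yr, scenario = scen)
        write_layer_csv(lay, file.path(outdir,
          sprintf("richness_%s_%s_%d.csv", g, gsub("[^A-Za-z0-9.-]", "_", scen), yr)))
      }
    }
  }
  cfg_json <- jsonlite::toJSON(result$config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "macrocast",
                   version = as.character(utils::packageVersion("macrocast")),
                   seed = result$config$seed,
                   config_md5 = unname(tools::md5sum(tf)),
                   config = jsonlite::fromJSON(cfg_json),
                   files = list(
                     summary = "summary.csv",
                     recompute = list(
                       mean_aoo_pct_change = "aoo_series.csv",
                       habitat_pct_change = "habitat_area.csv",
                       fraction_localities_losing_ge10pct = "richness_<group>_<scenario>_<year>.csv",
                       mean_local_diversity_change_pct = "richness_<group>_<scenario>_<year>.csv",
                       polar_share_pct = "regional_shares.csv")))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
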