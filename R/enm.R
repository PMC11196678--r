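# Ecological niche models: equal-size pseudo-absence sampling, monthly
# climatological feature construction, random forests with iterative
# variable elimination, and yearly suitability projection.

#' Sample pseudo-absences for a presence grid
#'
#' Draws `n` distinct cells uniformly without replacement from the
#' candidate domain (valid cells without occurrence records), keeping the
#' class sizes equal to the presence count by default.
#'
#' @param presence a `presence_grid`
#' @param candidate_mask logical matrix of candidate cells (typically
#'   light-valid ocean); presence cells are excluded automatically
#' @param n number of pseudo-absences (default: the presence-cell count)
#' @param seed integer seed
#' @return integer vector of cell (matrix linear) indices
#' @export
sample_pseudo_absences <- function(presence, candidate_mask,
                                   n = sum(presence$presence), seed = 1) {
  cand <- which(candidate_mask & !presence$presence)
  if (length(cand) < n)
    stop("insufficient pseudo-absence candidates: need ", n,
         ", have ", length(cand))
  with_seed(child_seed(seed, 47L), sort(sample(cand, n)))
}

#' Build the model feature table for a set of cells
#'
#' One feature per (dynamic variable, calendar month): for a multi-year
#' window the climatological mean of that calendar month over the window's
#' years (keeping the feature count identical between calibration and
#' projection), for a single year that year's monthly layer. Static
#' variables (depth, shortwave) are appended once. With the default five
#' dynamic and two static variables this yields 62 features.
#'
#' @param cells integer cell indices (matrix linear)
#' @param env a `synthetic_env` (or any object supporting [env_layer()])
#' @param years calibration window (e.g. `2015:2020`) or a single year
#' @param dynamic_vars,static_vars variable names
#' @param noise passed to [env_layer()]
#' @return data.frame of features (rows = cells, in input order); rows
#'   with any missing value are kept as `NA` for the caller to filter
#' @export
build_feature_table <- function(cells, env, years,
                                dynamic_vars = c("sst", "air_temp", "salinity",
                                                 "productivity", "ice_cover"),
                                static_vars = c("depth", "shortwave"),
                                noise = TRUE) {
  out <- list()
  for (v in dynamic_vars) {
    for (m in 1:12) {
      acc <- 0
      for (y in years) {
        layer <- env_layer(env, v, y, m, noise = noise)
        if (is.null(layer)) stop("missing layer: ", v, " ", y, "-", m)
        acc <- acc + layer[cells]
      }
      out[[sprintf("%s_m%02d", v, m)]] <- acc / length(years)
    }
  }
  for (v in static_vars) out[[v]] <- env$static[[v]][cells]
  as.data.frame(out)
}

#' Assemble a presence/pseudo-absence training table
#'
#' @param presence a `presence_grid`
#' @param absence_cells pseudo-absence cell indices
#'   ([sample_pseudo_absences()])
#' @param env environment providing the layers
#' @param years calibration window
#' @param ... passed to [build_feature_table()]
#' @return list with `x` (feature data.frame), `y` (0/1 factor) and
#'   `cells`; rows with missing features are dropped with a message
#' @export
training_table <- function(presence, absence_cells, env, years, ...) {
  p_cells <- which(presence$presence)
  cells <- c(p_cells, absence_cells)
  y <- factor(rep(c(1L, 0L), c(length(p_cells), length(absence_cells))),
              levels = c(0L, 1L))
  x <- build_feature_table(cells, env, years, ...)
  ok <- stats::complete.cases(x)
  if (any(!ok)) message(sum(!ok), " cells dropped for missing features")
  list(x = x[ok, , drop = FALSE], y = y[ok], cells = cells[ok])
}

.fit_rf <- function(x, y, num_trees, seed) {
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        probability = TRUE, importance = "impurity",
                        seed = seed, num.threads = 1,
                        respect.unordered.factors = TRUE)
  oob_p <- fit$predictions[, "1"]
  oob <- mean((oob_p >= 0.5) == (y == "1"), na.rm = TRUE)
  list(fit = fit, oob = oob, importance = fit$variable.importance)
}

#' Fit a random-forest niche model with iterative variable elimination
#'
#' Fits the full forest, then repeatedly removes the `drop_per_iter`
#' least-important features (mean impurity decrease; ties broken by
#' feature name for determinism) and refits, recording each step's
#' out-of-bag accuracy, until no further drop is possible. Returns the
#' most accurate model over all steps (ties resolved toward fewer
#' features). With `drop_per_iter >= ncol(x)` only the full model is
#' fitted — used for the group-level models, which keep all predictors.
#'
#' @param x feature data.frame
#' @param y 0/1 factor label (both classes must be present)
#' @param drop_per_iter features removed per iteration (default 10)
#' @param num_trees trees per forest (default 500)
#' @param seed integer seed (same seed and table give identical selected
#'   features)
#' @param label species or group label carried into the model
#' @return object of class `niche_model`: `label`, `forest` (the selected
#'   ranger fit), `selected_features`, `oob_score`, `importances`,
#'   `oob_trace` (data.frame of every step), `seed`
#' @export
fit_with_elimination <- function(x, y, drop_per_iter = 10, num_trees = 500,
                                 seed = 1, label = NA_character_) {
  y <- factor(y, levels = c(0L, 1L))
  if (length(unique(y)) < 2) stop("training table has a single class")
  feats <- sort(names(x))
  best <- NULL
  trace <- NULL
  step <- 0
  repeat {
    step <- step + 1
    m <- .fit_rf(x[, feats, drop = FALSE], y, num_trees, child_seed(seed, 53L))
    trace <- rbind(trace, data.frame(step = step, n_features = length(feats),
                                     oob = m$oob))
    take <- is.null(best) || m$oob > best$oob ||
      (m$oob == best$oob && length(feats) < length(best$features))
    if (take) best <- list(fit = m$fit, oob = m$oob, features = feats,
                           importance = m$importance)
    if (length(feats) <= drop_per_iter) break
    ord <- order(m$importance, names(m$importance))  # least important first
    feats <- sort(names(m$importance)[ord][-seq_len(drop_per_iter)])
  }
  structure(list(label = label, forest = best$fit,
                 selected_features = best$features,
                 oob_score = best$oob,
                 importances = best$importance,
                 oob_trace = trace, seed = seed),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model '%s': %d features selected, OOB accuracy %.3f (%d elimination steps)\n",
              x$label, length(x$selected_features), x$oob_score,
              nrow(x$oob_trace)))
  invisible(x)
}

#' Project a niche model onto one year's layers
#'
#' Builds that year's monthly features for every cell of `cells` and
#' predicts the probability of occurrence; cells with missing inputs are
#' masked.
#'
#' @param model a [fit_with_elimination()] result
#' @param env environment providing the layers
#' @param year projection year
#' @param cells cell indices to predict on (typically the light-valid
#'   cells); default all valid ocean cells
#' @param noise passed to the layer evaluation
#' @return object of class `suitability_map`: `label`, `grid`, `year`,
#'   `scenario`, `p` (matrix in \[0, 1\], `NA` off the predicted cells)
#' @export
project_suitability <- function(model, env, year, cells = NULL, noise = TRUE) {
  if (is.null(cells)) cells <- which(env$ocean)
  x <- build_feature_table(cells, env, year, noise = noise)
  missing <- setdiff(model$selected_features, names(x))
  if (length(missing))
    stop("layers do not supply selected features: ",
         paste(missing, collapse = ", "))
  x <- x[, model$selected_features, drop = FALSE]
  ok <- stats::complete.cases(x)
  p <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  if (any(ok)) {
    pred <- stats::predict(model$forest, data = x[ok, , drop = FALSE],
                           num.threads = 1)$predictions[, "1"]
    p[cells[ok]] <- pred
  }
  structure(list(label = model$label, grid = env$grid, year = year,
                 scenario = env$scenario$label, p = p),
            class = "suitability_map")
}
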