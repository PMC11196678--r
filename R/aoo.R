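# Area of occupancy: probability-weighted extents inside the fixed
# present-day extent of occurrence, proportional-expansion alternatives,
# and group-mean trajectories.

#' Area-of-occupancy extent of one suitability map
#'
#' Probability-weighted area: the sum over the extent-of-occurrence cells
#' of `p * cell_area`. Cells with masked probabilities are skipped.
#'
#' @param suit a `suitability_map` or probability matrix
#' @param eoo an `eoo_mask` (or logical matrix)
#' @param areas cell-area matrix
#' @return extent in km^2 (0, with a warning, for an empty EOO)
#' @export
aoo_extent <- function(suit, eoo, areas) {
  p <- if (inherits(suit, "suitability_map")) suit$p else suit
  m <- if (inherits(eoo, "eoo_mask")) eoo$mask else eoo
  if (!any(m)) {
    warning("empty extent of occurrence; area of occupancy is 0")
    return(0)
  }
  sel <- m & !is.na(p)
  sum(p[sel] * areas[sel])
}

#' Probability-weighted suitable area of a species
#'
#' The operational definition of the suitable area `s`: the sum of
#' `p * cell_area` over all light-valid cells (not just the extent of
#' occurrence), dimensionally consistent with [aoo_extent()] so the
#' occupied-to-suitable ratio is a clean fraction. A thresholded
#' alternative is available via `threshold`.
#'
#' @param suit a `suitability_map` or probability matrix
#' @param light_valid logical validity matrix
#' @param areas cell-area matrix
#' @param threshold if not `NULL`, use the binary area at `p >= threshold`
#'   instead of the probability weighting
#' @return suitable area in km^2
#' @export
suitable_area_weighted <- function(suit, light_valid, areas, threshold = NULL) {
  p <- if (inherits(suit, "suitability_map")) suit$p else suit
  if (!is.null(threshold)) return(suitable_area(p, threshold, light_valid, areas))
  sel <- light_valid & !is.na(p)
  sum(p[sel] * areas[sel])
}

#' Area of occupancy under the proportional-expansion hypothesis
#'
#' A species is assumed to colonize newly suitable area in proportion to
#' its baseline occupied-to-suitable ratio `R_2015 = aoo_2015 / s_2015`:
#' the projected occupancy in year Y is `R_2015 * s_Y`. At the baseline
#' year this returns `aoo_2015` exactly.
#'
#' @param aoo_2015 baseline area of occupancy (km^2)
#' @param s_2015 baseline suitable area (km^2), must be positive
#' @param s_year suitable area in the projection year (km^2)
#' @return projected area of occupancy (km^2)
#' @export
proportional_expansion <- function(aoo_2015, s_2015, s_year) {
  if (s_2015 <= 0) stop("baseline suitable area must be positive")
  (aoo_2015 / s_2015) * s_year
}

#' Group-mean area-of-occupancy trajectory
#'
#' Per year, the unweighted mean and cross-species standard error of the
#' per-species extents (km^2) and of the per-species percent change
#' relative to the first year (percentages computed per species, then
#' averaged); both aggregated into 5-year bins.
#'
#' @param aoo matrix: species x years (dimnames: species ids, years)
#' @return list with `km2` and `pct` data.frames (`year`, `mean`, `se`,
#'   binned columns as attribute `"binned"`, as in
#'   [mean_local_change_trajectory()])
#' @export
mean_aoo_trajectory <- function(aoo) {
  stopifnot(is.matrix(aoo), nrow(aoo) >= 1)
  years <- as.integer(colnames(aoo))
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  mk <- function(M) {
    m <- colMeans(M)
    s <- apply(M, 2, se)
    out <- data.frame(year = years, mean = m, se = s, row.names = NULL)
    attr(out, "binned") <- bin_trajectory(years, m, s)
    out
  }
  pct <- 100 * sweep(aoo, 1, aoo[, 1], `/`) - 100
  list(km2 = mk(aoo), pct = mk(pct))
}

#' Distribution of per-species area-of-occupancy change at end of century
#'
#' Per-species percent change between the last and first year, binned into
#' a histogram, with a moment skewness statistic: real projections tend to
#' pile most species at small losses with a long tail of severe ones
#' (negative skew).
#'
#' @param aoo species x years matrix (as in [mean_aoo_trajectory()])
#' @param breaks histogram breaks in percent (default 10-point bins
#'   spanning the data)
#' @return list with `pct_change` (named vector), `hist` (histogram
#'   object) and `skewness`
#' @export
per_species_loss_distribution <- function(aoo, breaks = NULL) {
  pct <- 100 * (aoo[, ncol(aoo)] / aoo[, 1]) - 100
  if (is.null(breaks)) {
    lo <- 10 * floor(min(pct) / 10); hi <- 10 * ceiling(max(pct) / 10)
    if (lo == hi) hi <- lo + 10
    breaks <- seq(lo, hi, by = 10)
  }
  h <- graphics::hist(pct, breaks = breaks, plot = FALSE)
  m <- mean(pct); s <- stats::sd(pct)
  skew <- if (is.na(s) || s == 0) 0 else mean((pct - m)^3) / s^3
  list(pct_change = pct, hist = h, skewness = skew)
}
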