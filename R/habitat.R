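# Group-level habitat extent: thresholded suitable area, percent change,
# and shares across marine regions.

#' Suitable habitat area at a probability threshold
#'
#' Total area (km^2) of the light-valid cells whose probability of
#' occurrence is at least `threshold` (inclusive boundary).
#'
#' @param suit a `suitability_map` or a probability matrix
#' @param threshold probability threshold in (0, 1)
#' @param light_valid logical validity matrix
#' @param areas cell-area matrix ([cell_area()])
#' @return area in km^2
#' @export
suitable_area <- function(suit, threshold, light_valid, areas) {
  p <- if (inherits(suit, "suitability_map")) suit$p else suit
  stopifnot(threshold > 0, threshold < 1)
  sel <- light_valid & !is.na(p) & p >= threshold
  sum(areas[sel])
}

#' Percent change in habitat area relative to a baseline
#'
#' `100 * (area_end - area_start) / area_start`; a vanished habitat is
#' -100. Undefined (with a warning) when the baseline is zero.
#'
#' @param area_end,area_start areas in km^2
#' @return percent change, `NA` if `area_start` is 0
#' @export
pct_change_area <- function(area_end, area_start) {
  if (area_start == 0) {
    warning("baseline area is zero; percent change undefined")
    return(NA_real_)
  }
  100 * (area_end - area_start) / area_start
}

#' Synthetic marine-region label raster
#'
#' Twelve regions standing in for the world marine ecoregions: three
#' latitude bands (tropical < 30, temperate 30-60, polar >= 60 degrees
#' absolute latitude) crossed with four 90-degree longitude quadrants.
#' Every cell gets a label; callers restrict to ocean via their own masks.
#'
#' @param grid a [grid_spec()]
#' @return list with `labels` (integer matrix, 1-12) and `legend`
#'   (data.frame `id`, `name`, `band`, `quadrant`)
#' @export
region_mask <- function(grid) {
  LAT <- lat_field(grid); LON <- lon_field(grid)
  band <- ifelse(abs(LAT) < 30, 1L, ifelse(abs(LAT) < 60, 2L, 3L))
  quad <- pmin(floor((LON + 180) / 90) + 1L, 4L)
  labels <- (band - 1L) * 4L + quad
  bands <- c("tropical", "temperate", "polar")
  legend <- data.frame(
    id = 1:12,
    name = paste0(rep(bands, each = 4), "_q", rep(1:4, 3)),
    band = rep(bands, each = 4),
    quadrant = rep(1:4, 3))
  list(labels = labels, legend = legend)
}

#' Regional shares of suitable habitat
#'
#' The share of the global suitable area (at `threshold`) falling in each
#' marine region. Shares over labelled suitable cells sum to 100%;
#' unlabelled suitable cells, if any, are reported separately.
#'
#' @param suit a `suitability_map` or probability matrix
#' @param regions a [region_mask()] (or compatible list with `labels`,
#'   `legend`)
#' @param threshold probability threshold (default 0.6, chosen so every
#'   region keeps at least one suitable cell)
#' @param light_valid logical validity matrix
#' @param areas cell-area matrix
#' @return list with `shares` (data.frame `id`, `name`, `area_km2`,
#'   `share_pct`), `global_km2` and `unlabeled_km2`
#' @export
regional_shares <- function(suit, regions, threshold = 0.6, light_valid, areas) {
  p <- if (inherits(suit, "suitability_map")) suit$p else suit
  sel <- light_valid & !is.na(p) & p >= threshold
  total <- sum(areas[sel])
  if (total == 0) stop("no suitable cells at threshold ", threshold)
  lab <- regions$labels[sel]
  a <- areas[sel]
  labeled <- !is.na(lab)
  by_region <- tapply(a[labeled], factor(lab[labeled], levels = regions$legend$id), sum)
  by_region[is.na(by_region)] <- 0
  labeled_total <- sum(by_region)
  shares <- data.frame(regions$legend[, c("id", "name")],
                       area_km2 = as.numeric(by_region),
                       share_pct = 100 * as.numeric(by_region) / labeled_total)
  list(shares = shares, global_km2 = total,
       unlabeled_km2 = total - labeled_total)
}
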