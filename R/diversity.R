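# Stacked-SDM diversity: richness maps from per-species area-of-occupancy
# maps, symmetric (log-e percentage) change, trajectories, latitudinal
# profiles and locality-loss fractions.

#' Clip a suitability map by an extent-of-occurrence mask
#'
#' The no-dispersal assumption: a species' probability of occurrence is
#' kept only inside its present-day extent of occurrence and is zero
#' outside it. The result is the species' area-of-occupancy map.
#'
#' @param suit a `suitability_map`
#' @param eoo an `eoo_mask` on the same grid
#' @return matrix of clipped probabilities (0 outside the EOO, `NA` only
#'   where the suitability itself is masked inside the EOO)
#' @export
clip_by_eoo <- function(suit, eoo) {
  stopifnot(identical(suit$grid, eoo$grid))
  p <- suit$p
  p[!eoo$mask] <- 0
  p
}

#' Stack per-species area-of-occupancy maps into a richness map
#'
#' Species richness per cell is the sum over species of the probability of
#' occurrence; masked probabilities count as zero and richness is exactly
#' zero outside the union of the species' extents.
#'
#' @param aoo_maps list of clipped probability matrices (see
#'   [clip_by_eoo()]) on one grid
#' @return richness matrix
#' @export
stack_richness <- function(aoo_maps) {
  stopifnot(length(aoo_maps) >= 1)
  d <- dim(aoo_maps[[1]])
  Reduce(`+`, lapply(aoo_maps, function(p) {
    if (!all(dim(p) == d)) stop("grid mismatch between stacked maps")
    ifelse(is.na(p), 0, p)
  }))
}

#' Log-e percentage change between two maps
#'
#' `100 * ln(end / start)`, the symmetric gain/loss scale: halving is
#' -69.31, doubling +69.31. Cells where either map is below `epsilon`
#' (default 1e-6 species) are masked, so near-empty cells do not produce
#' unbounded ratios.
#'
#' @param d_end,d_start matrices on one grid
#' @param epsilon minimum value for a cell to enter the ratio
#' @return matrix of log-e percentage changes (`NA` where masked)
#' @export
log_pct_change <- function(d_end, d_start, epsilon = 1e-6) {
  stopifnot(all(dim(d_end) == dim(d_start)))
  ok <- !is.na(d_end) & !is.na(d_start) & d_end > epsilon & d_start > epsilon
  out <- matrix(NA_real_, nrow(d_end), ncol(d_end))
  # log difference form keeps antisymmetry exact under argument swap
  out[ok] <- 100 * (log(d_end[ok]) - log(d_start[ok]))
  out
}

#' Fraction of occupied localities losing a given share of diversity
#'
#' Of the cells occupied at the start (`d_start > 0`), the fraction whose
#' relative loss `(d_start - d_end) / d_start` is at least `loss_frac`.
#'
#' @param d_start,d_end richness matrices
#' @param loss_frac loss threshold (default 0.10)
#' @return scalar fraction in \[0, 1\]
#' @export
fraction_losing <- function(d_start, d_end, loss_frac = 0.10) {
  occ <- !is.na(d_start) & d_start > 0
  if (!any(occ)) stop("no occupied localities in the start map")
  loss <- (d_start[occ] - d_end[occ]) / d_start[occ]
  loss[is.na(loss)] <- 0
  mean(loss >= loss_frac)
}

.bin_5yr <- function(years) 5 * ((years - years[1]) %/% 5) + years[1]

#' Aggregate yearly statistics into 5-year bins
#'
#' Bins are `[2015-2019], [2020-2024], ...`, labelled by the bin start;
#' binned mean and SE are the means of the yearly values in the bin, and
#' the 95% CI is `mean +/- 1.96 * se` (normal approximation).
#'
#' @param years vector of years
#' @param mean_y,se_y yearly means and standard errors
#' @return data.frame `bin`, `mean`, `se`, `ci_low`, `ci_high`
#' @export
bin_trajectory <- function(years, mean_y, se_y) {
  bin <- .bin_5yr(years)
  agg <- function(v) tapply(v, bin, mean)
  m <- agg(mean_y); s <- agg(se_y)
  data.frame(bin = as.integer(names(m)), mean = as.numeric(m),
             se = as.numeric(s),
             ci_low = as.numeric(m - 1.96 * s),
             ci_high = as.numeric(m + 1.96 * s),
             row.names = NULL)
}

#' Trajectory of mean local diversity change
#'
#' For every year, the log-e percentage change of each occupied cell's
#' richness relative to the baseline year, averaged across cells (with a
#' cross-cell standard error); then aggregated into 5-year bins. Means are
#' unweighted across cells. Cells are not spatially decorrelated, so the
#' CI describes the cell ensemble, not independent localities.
#'
#' @param richness_by_year named list (names = years) of richness matrices
#' @param epsilon mask threshold passed to [log_pct_change()]
#' @return data.frame `year`, `mean`, `se` plus the binned columns of
#'   [bin_trajectory()] as attribute `"binned"`
#' @export
mean_local_change_trajectory <- function(richness_by_year, epsilon = 1e-6) {
  years <- as.integer(names(richness_by_year))
  base <- richness_by_year[[1]]
  res <- lapply(richness_by_year, function(r) {
    ch <- log_pct_change(r, base, epsilon)
    v <- ch[!is.na(ch)]
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  })
  m <- vapply(res, `[[`, 0, "mean")
  s <- vapply(res, `[[`, 0, "se")
  s[is.na(s)] <- 0  # single-cell or constant fields
  out <- data.frame(year = years, mean = m, se = s, row.names = NULL)
  attr(out, "binned") <- bin_trajectory(years, m, s)
  out
}

#' Latitudinal profile of a change map
#'
#' Unweighted mean over the valid cells of each latitude row; rows without
#' valid cells are `NA`.
#'
#' @param change matrix on `grid`
#' @param grid the [grid_spec()] of the map
#' @return data.frame `lat` (row-center latitude), `mean`, `n_cells`
#' @export
latitudinal_profile <- function(change, grid) {
  lat <- grid_centers(grid)$lat
  n <- rowSums(!is.na(change))
  m <- rowMeans(change, na.rm = TRUE)
  m[n == 0] <- NA_real_
  data.frame(lat = lat, mean = m, n_cells = n, row.names = NULL)
}
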