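#' Regular latitude/longitude grid specification
#'
#' Defines a regular geographic grid with half-open cells
#' `[lat, lat + res) x [lon, lon + res)`; cell centers sit at
#' `lat + res/2`, `lon + res/2`. Rows run south to north, columns west to
#' east, so a layer on the grid is an `n_rows x n_cols` matrix whose
#' `[1, 1]` cell is the south-western corner.
#'
#' Longitudes must lie in `[-180, 180]`; grids crossing the antimeridian
#' are rejected rather than silently wrapped.
#'
#' @param resolution_deg cell size in decimal degrees (default 0.5)
#' @param lat_min,lat_max,lon_min,lon_max grid bounds in degrees; the spans
#'   must be integer multiples of `resolution_deg`
#' @return an object of class `grid_spec` with fields `resolution_deg`,
#'   bounds, `n_rows`, `n_cols`
#' @export
grid_spec <- function(resolution_deg = 0.5,
                      lat_min = -90, lat_max = 90,
                      lon_min = -180, lon_max = 180) {
  stopifnot(resolution_deg > 0, lat_max > lat_min, lon_max > lon_min)
  if (lat_min < -90 || lat_max > 90)
    stop("latitude bounds must lie in [-90, 90]")
  if (lon_min < -180 || lon_max > 180)
    stop("longitude bounds must lie in [-180, 180]; antimeridian-crossing grids are not supported")
  n_rows <- (lat_max - lat_min) / resolution_deg
  n_cols <- (lon_max - lon_min) / resolution_deg
  if (abs(n_rows - round(n_rows)) > 1e-9 || abs(n_cols - round(n_cols)) > 1e-9)
    stop("grid spans must be integer multiples of resolution_deg")
  structure(list(resolution_deg = resolution_deg,
                 lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max,
                 n_rows = as.integer(round(n_rows)),
                 n_cols = as.integer(round(n_cols))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %.4g deg, lat [%g, %g], lon [%g, %g], %d x %d cells\n",
              x$resolution_deg, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
              x$n_rows, x$n_cols))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [grid_spec()]
#' @return list with `lat` (length `n_rows`) and `lon` (length `n_cols`)
#'   center vectors
#' @export
grid_centers <- function(grid) {
  res <- grid$resolution_deg
  list(lat = grid$lat_min + res * (seq_len(grid$n_rows) - 0.5),
       lon = grid$lon_min + res * (seq_len(grid$n_cols) - 0.5))
}

#' Matrix of cell-center latitudes (n_rows x n_cols)
#' @param grid a [grid_spec()]
#' @return matrix of latitudes
#' @export
lat_field <- function(grid) {
  matrix(grid_centers(grid)$lat, grid$n_rows, grid$n_cols)
}

#' Matrix of cell-center longitudes (n_rows x n_cols)
#' @param grid a [grid_spec()]
#' @return matrix of longitudes
#' @export
lon_field <- function(grid) {
  matrix(grid_centers(grid)$lon, grid$n_rows, grid$n_cols, byrow = TRUE)
}

#' Locate points on a grid
#'
#' Assigns each (lon, lat) point to a cell using the half-open cell
#' convention: a point on a cell's southern or western edge belongs to that
#' cell. Points outside the bounds (including points exactly on `lat_max`
#' or `lon_max`) get `NA`.
#'
#' @param grid a [grid_spec()]
#' @param lon,lat coordinate vectors (degrees)
#' @return integer vector of matrix linear indices (row-major within column,
#'   as R stores matrices), `NA` for out-of-bounds points
#' @export
cell_index <- function(grid, lon, lat) {
  res <- grid$resolution_deg
  row <- floor((lat - grid$lat_min) / res) + 1
  col <- floor((lon - grid$lon_min) / res) + 1
  ok <- row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  idx <- ifelse(ok, (col - 1L) * grid$n_rows + row, NA_integer_)
  as.integer(idx)
}

#' Environmental raster layer on a grid
#'
#' A single 2-D field with variable metadata. `NA` entries in `values`
#' mark invalid (e.g. land) cells.
#'
#' @param grid a [grid_spec()]
#' @param values `n_rows x n_cols` numeric matrix (`NA` = invalid)
#' @param variable variable name (e.g. `"sst"`)
#' @param units unit string (e.g. `"degC"`)
#' @param year,month temporal coordinates, or `NULL` for static layers
#' @param scenario scenario label or `NULL`
#' @return an object of class `raster_layer`
#' @export
raster_layer <- function(grid, values, variable, units = "",
                         year = NULL, month = NULL, scenario = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be an n_rows x n_cols matrix for the grid")
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite wherever not NA")
  if (identical(variable, "ice_cover") &&
      any(values < 0 | values > 100, na.rm = TRUE))
    stop("ice_cover must lie in [0, 100]")
  if (identical(variable, "light_bottom") && any(values < 0, na.rm = TRUE))
    stop("light_bottom must be non-negative")
  structure(list(grid = grid, values = values, variable = variable,
                 units = units, year = year, month = month,
                 scenario = scenario),
            class = "raster_layer")
}

#' Spherical cell areas of a grid
#'
#' Cell area on the authalic sphere (radius 6371.0 km) from the spherical
#' band formula `A = R^2 * dlon * (sin(lat2) - sin(lat1))`. Area depends on
#' latitude only; the areas of a full global grid sum to the sphere's
#' surface `4*pi*R^2`.
#'
#' @param grid a [grid_spec()]
#' @return `n_rows x n_cols` matrix of areas in km^2
#' @export
cell_area <- function(grid) {
  R <- 6371.0
  res <- grid$resolution_deg
  lat1 <- grid$lat_min + res * (seq_len(grid$n_rows) - 1)
  band <- R^2 * (res * pi / 180) * (sin((lat1 + res) * pi / 180) - sin(lat1 * pi / 180))
  matrix(band, grid$n_rows, grid$n_cols)
}

#' Regrid a layer onto a target grid
#'
#' Three methods: `"nearest"` (nearest source cell center), `"bilinear"`
#' (bilinear interpolation between source cell centers, clamped at the
#' source margin) and `"block_mean"` (area-weighted mean of the source
#' cells nested in each target cell; requires the target resolution to be
#' an integer multiple of the source resolution with aligned bounds).
#' Constant fields are reproduced exactly under every method, and
#' `block_mean` conserves the area-weighted global mean of a fully valid
#' field.
#'
#' For `nearest` and `bilinear`, target cells whose (interpolated) source
#' cells are invalid become `NA`; `block_mean` averages the valid source
#' cells in the block and is `NA` only when all of them are.
#'
#' @param layer a [raster_layer()]
#' @param target a [grid_spec()] overlapping the source grid
#' @param method one of `"nearest"`, `"bilinear"`, `"block_mean"`
#' @return a [raster_layer()] on `target`
#' @export
regrid <- function(layer, target, method = c("bilinear", "nearest", "block_mean")) {
  method <- match.arg(method)
  src <- layer$grid
  if (src$lat_max <= target$lat_min || target$lat_max <= src$lat_min ||
      src$lon_max <= target$lon_min || target$lon_max <= src$lon_min)
    stop("source and target grids do not overlap")
  out <- switch(method,
    nearest = .regrid_nearest(layer$values, src, target),
    bilinear = .regrid_bilinear(layer$values, src, target),
    block_mean = .regrid_block_mean(layer$values, src, target))
  raster_layer(target, out, layer$variable, layer$units,
               year = layer$year, month = layer$month, scenario = layer$scenario)
}

.regrid_nearest <- function(v, src, tgt) {
  tc <- grid_centers(tgt)
  sc <- grid_centers(src)
  ri <- pmin(pmax(vapply(tc$lat, function(x) which.min(abs(sc$lat - x)), 1L), 1L), src$n_rows)
  ci <- pmin(pmax(vapply(tc$lon, function(x) which.min(abs(sc$lon - x)), 1L), 1L), src$n_cols)
  v[ri, ci, drop = FALSE]
}

.regrid_bilinear <- function(v, src, tgt) {
  tc <- grid_centers(tgt)
  sc <- grid_centers(src)
  interp_axis <- function(x, centers) {
    # returns lower index and weight of upper neighbour, clamped at margins
    i <- findInterval(x, centers)
    i0 <- pmin(pmax(i, 1L), length(centers) - 1L)
    w <- (x - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, w = w)
  }
  if (src$n_rows < 2L || src$n_cols < 2L)
    return(.regrid_nearest(v, src, tgt))
  a <- interp_axis(tc$lat, sc$lat)
  b <- interp_axis(tc$lon, sc$lon)
  wr <- a$w; wc <- b$w
  v00 <- v[a$i0, b$i0, drop = FALSE]
  v10 <- v[a$i0 + 1L, b$i0, drop = FALSE]
  v01 <- v[a$i0, b$i0 + 1L, drop = FALSE]
  v11 <- v[a$i0 + 1L, b$i0 + 1L, drop = FALSE]
  WR <- matrix(wr, length(wr), length(wc))
  WC <- matrix(wc, length(wr), length(wc), byrow = TRUE)
  v00 * (1 - WR) * (1 - WC) + v10 * WR * (1 - WC) +
    v01 * (1 - WR) * WC + v11 * WR * WC
}

.regrid_block_mean <- function(v, src, tgt) {
  k <- tgt$resolution_deg / src$resolution_deg
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("block_mean requires the target resolution to be an integer multiple of the source resolution")
  k <- as.integer(round(k))
  aligned <- function(a, b, res) abs((a - b) / res - round((a - b) / res)) < 1e-9
  if (!aligned(tgt$lat_min, src$lat_min, src$resolution_deg) ||
      !aligned(tgt$lon_min, src$lon_min, src$resolution_deg))
    stop("block_mean requires aligned grid origins")
  area <- cell_area(src)
  w <- ifelse(is.na(v), 0, area)
  roff <- as.integer(round((tgt$lat_min - src$lat_min) / src$resolution_deg))
  coff <- as.integer(round((tgt$lon_min - src$lon_min) / src$resolution_deg))
  out <- matrix(NA_real_, tgt$n_rows, tgt$n_cols)
  for (i in seq_len(tgt$n_rows)) {
    rs <- roff + (i - 1L) * k + seq_len(k)
    rs <- rs[rs >= 1 & rs <= src$n_rows]
    if (!length(rs)) next
    for (j in seq_len(tgt$n_cols)) {
      cs <- coff + (j - 1L) * k + seq_len(k)
      cs <- cs[cs >= 1 & cs <= src$n_cols]
      if (!length(cs)) next
      wt <- sum(w[rs, cs])
      if (wt > 0) {
        # anchored weighted mean: exact for constant fields
        vb <- v[rs, cs]; wb <- w[rs, cs]
        v0 <- vb[wb > 0][1]
        out[i, j] <- v0 + sum(wb * (ifelse(is.na(vb), 0, vb) - v0)) / wt
      }
    }
  }
  out
}

#' Photosynthesis light mask
#'
#' Cells with enough light at the seabed for macrophyte photosynthesis:
#' `TRUE` exactly where light-at-bottom is at least `threshold`
#' (E m^-2 yr^-1) and the cell is valid ocean. Cells below the threshold
#' are uninhabitable for benthic macrophytes and are excluded from every
#' downstream extent.
#'
#' @param light_bottom a [raster_layer()] with `variable == "light_bottom"`
#' @param threshold minimum yearly seabed irradiance (default 50 E m^-2 yr^-1);
#'   the boundary is inclusive (a cell at exactly the threshold is suitable)
#' @return `n_rows x n_cols` logical matrix
#' @export
light_mask <- function(light_bottom, threshold = 50) {
  if (!identical(light_bottom$variable, "light_bottom"))
    stop("light_mask expects a light_bottom layer, got ", light_bottom$variable)
  m <- !is.na(light_bottom$values) & light_bottom$values >= threshold
  m
}

#' Write a raster layer as plain text
#'
#' The package's text raster format: `#`-prefixed metadata header
#' (grid bounds, resolution, variable, units, time, scenario) followed by a
#' `row,col,value` CSV of the valid cells. Round-trips exactly through
#' [read_layer_csv()].
#'
#' @param layer a [raster_layer()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_layer_csv <- function(layer, path) {
  g <- layer$grid
  hdr <- c(
    sprintf("# macrocast raster v1"),
    sprintf("# resolution_deg=%.17g lat_min=%.17g lat_max=%.17g lon_min=%.17g lon_max=%.17g",
            g$resolution_deg, g$lat_min, g$lat_max, g$lon_min, g$lon_max),
    sprintf("# variable=%s units=%s year=%s month=%s scenario=%s",
            layer$variable, layer$units,
            if (is.null(layer$year)) "NA" else layer$year,
            if (is.null(layer$month)) "NA" else layer$month,
            if (is.null(layer$scenario)) "NA" else layer$scenario))
  idx <- which(!is.na(layer$values), arr.ind = TRUE)
  df <- data.frame(row = idx[, 1], col = idx[, 2],
                   value = layer$values[idx])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a raster layer written by [write_layer_csv()]
#'
#' @param path file path
#' @return a [raster_layer()]
#' @export
read_layer_csv <- function(path) {
  lines <- readLines(path, n = 3)
  if (!startsWith(lines[1], "# macrocast raster"))
    stop("not a macrocast raster text file: ", path)
  kv <- function(line) {
    toks <- strsplit(sub("^# ", "", line), " ")[[1]]
    parts <- strsplit(toks, "=")
    stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
  }
  g <- kv(lines[2]); m <- kv(lines[3])
  grid <- grid_spec(as.numeric(g["resolution_deg"]),
                    as.numeric(g["lat_min"]), as.numeric(g["lat_max"]),
                    as.numeric(g["lon_min"]), as.numeric(g["lon_max"]))
  df <- utils::read.csv(path, comment.char = "#")
  v <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  v[cbind(df$row, df$col)] <- df$value
  num_or_null <- function(x) if (identical(x, "NA")) NULL else as.numeric(x)
  raster_layer(grid, v, m[["variable"]], m[["units"]],
               year = num_or_null(m[["year"]]),
               month = num_or_null(m[["month"]]),
               scenario = if (identical(m[["scenario"]], "NA")) NULL else m[["scenario"]])
}
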