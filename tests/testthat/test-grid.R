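test_that("grid_spec validates bounds and resolution multiples", {
  g <- grid_spec(0.5)
  expect_equal(g$n_rows, 360L)
  expect_equal(g$n_cols, 720L)
  expect_error(grid_spec(0.7, 0, 1, 0, 1), "integer multiples")
  expect_error(grid_spec(1, -91, 0, 0, 10), "latitude")
  expect_error(grid_spec(1, 0, 10, 170, 190), "antimeridian|longitude")
  cen <- grid_centers(grid_spec(2, 0, 10, 0, 10))
  expect_equal(cen$lat, c(1, 3, 5, 7, 9))
})

test_that("cell_index follows the half-open cell convention", {
  g <- grid_spec(1, 0, 10, 0, 10)
  # point exactly on a cell's south-west corner belongs to that cell
  expect_equal(cell_index(g, 3, 4), cell_index(g, 3.5, 4.5))
  # upper bounds are exclusive
  expect_true(is.na(cell_index(g, 10, 5)))
  expect_true(is.na(cell_index(g, 5, 10)))
  expect_false(is.na(cell_index(g, 0, 0)))
})

test_that("cell areas close to the sphere surface and depend on latitude only", {
  g <- grid_spec(0.5)
  a <- cell_area(g)
  expect_equal(sum(a), 4 * pi * 6371^2, tolerance = 1e-6)
  # symmetry about the equator
  expect_equal(a[1, 1], a[g$n_rows, 1])
  expect_true(all(a > 0))
  # strict decrease of band area with |latitude|
  band <- a[, 1]
  north <- band[(g$n_rows / 2 + 1):g$n_rows]
  expect_true(all(diff(north) < 0))
  # quadrature oracle for the 0.5-degree cell straddling the equator
  band_area <- function(lat1, lat2, dlon_deg) {
    f <- stats::integrate(function(phi) cos(phi), lat1 * pi / 180, lat2 * pi / 180,
                          rel.tol = 1e-12)
    6371^2 * (dlon_deg * pi / 180) * f$value
  }
  eq_row <- g$n_rows / 2 + 1  # cell [0, 0.5)
  expect_equal(a[eq_row, 1], band_area(0, 0.5, 0.5), tolerance = 1e-9)
})

test_that("regrid preserves constants, averages blocks, and propagates masks", {
  src <- grid_spec(0.25, 0, 10, 0, 10)
  tgt <- grid_spec(0.5, 0, 10, 0, 10)
  const <- raster_layer(src, matrix(7, src$n_rows, src$n_cols), "sst", "degC")
  for (m in c("nearest", "bilinear", "block_mean")) {
    out <- regrid(const, tgt, m)
    expect_true(all(out$values == 7), info = m)
  }
  # block_mean of the latitude field equals the area-weighted child mean
  latf <- raster_layer(src, lat_field(src), "sst", "degC")
  out <- regrid(latf, tgt, "block_mean")
  a <- cell_area(src)
  manual <- sum(lat_field(src)[1:2, 1:2] * a[1:2, 1:2]) / sum(a[1:2, 1:2])
  expect_equal(out$values[1, 1], manual, tolerance = 1e-12)
  # all-missing source stays missing
  nas <- raster_layer(src, matrix(NA_real_, src$n_rows, src$n_cols), "sst", "degC")
  for (m in c("nearest", "bilinear", "block_mean"))
    expect_true(all(is.na(regrid(nas, tgt, m)$values)), info = m)
  # non-overlapping grids are rejected
  far <- grid_spec(0.5, 40, 50, 40, 50)
  expect_error(regrid(const, far), "overlap")
})

test_that("block_mean regridding conserves the area-weighted global mean", {
  src <- grid_spec(1)
  tgt <- grid_spec(2)
  set.seed(1)
  v <- matrix(rnorm(src$n_rows * src$n_cols, 10), src$n_rows, src$n_cols)
  lay <- raster_layer(src, v, "sst", "degC")
  out <- regrid(lay, tgt, "block_mean")
  wmean <- function(x, g) sum(x * cell_area(g)) / sum(cell_area(g))
  expect_equal(wmean(out$values, tgt), wmean(v, src), tolerance = 1e-9)
})

test_that("light mask uses an inclusive 50 threshold and is anti-monotone", {
  g <- grid_spec(1, 0, 2, 0, 2)
  v <- matrix(c(49.999, 50, 120, NA), 2, 2)
  lay <- raster_layer(g, v, "light_bottom", "E m-2 yr-1")
  m <- light_mask(lay)
  expect_false(m[1, 1])   # just under the threshold is uninhabitable
  expect_true(m[2, 1])    # exactly at the threshold is habitable
  expect_true(m[1, 2])
  expect_false(m[2, 2])   # land stays invalid
  # all-land raster gives an all-false mask
  land <- raster_layer(g, matrix(NA_real_, 2, 2), "light_bottom", "")
  expect_false(any(light_mask(land)))
  # raising the threshold never adds cells
  m80 <- light_mask(lay, 80)
  expect_true(all(m | !m80))
  expect_error(light_mask(raster_layer(g, v, "sst", "degC")), "light_bottom")
})

test_that("raster text format round-trips values, mask and metadata", {
  g <- grid_spec(2, -10, 10, 0, 20)
  v <- matrix(runif(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  v[3, ] <- NA
  lay <- raster_layer(g, v, "salinity", "PSU", year = 2020, month = 6,
                      scenario = "test")
  f <- tempfile(fileext = ".csv")
  write_layer_csv(lay, f)
  back <- read_layer_csv(f)
  expect_equal(back$values, v)
  expect_identical(back$variable, "salinity")
  expect_equal(back$year, 2020)
  expect_identical(back$scenario, "test")
  expect_equal(back$grid$resolution_deg, 2)
})
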