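test_that("climate_grid enforces physical invariants by masking", {
  set.seed(1)
  cell <- random_cell()
  g <- uniform_grid(cell, nlat = 3, nlon = 3)
  expect_s3_class(g, "climate_grid")
  expect_true(all(g$land_mask))
  expect_true(all(g$tmax >= g$tmin))

  # one cell with rh = 1.2 gets masked with a count in the warning
  bad_rh09 <- g$rh09
  bad_rh09[2, 2, 5] <- 1.2
  expect_warning(
    g2 <- climate_grid(g$lons, g$lats, g$tmin, g$tmax, g$precip,
                       bad_rh09, g$rh15),
    "1 cell")
  expect_false(g2$land_mask[2, 2])
  expect_equal(sum(g2$land_mask), 8)
  expect_true(all(is.na(g2$rh09[2, 2, ])))

  # tmax < tmin likewise masks rather than errors
  bad_tmax <- g$tmax
  bad_tmax[1, 1, 1] <- g$tmin[1, 1, 1] - 1
  expect_warning(
    g3 <- climate_grid(g$lons, g$lats, g$tmin, bad_tmax, g$precip,
                       g$rh09, g$rh15),
    "masked")
  expect_false(g3$land_mask[1, 1])
})

test_that("latitude order is normalized to descending", {
  set.seed(2)
  cell <- random_cell()
  lats_up <- c(10, 12, 14)
  lons <- c(0, 2)
  arr <- array(rep(cell$precip, each = 6), c(3, 2, 12))
  tmin <- array(rep(cell$tmin, each = 6), c(3, 2, 12))
  tmin[1, , ] <- tmin[1, , ] - 5  # tag the southernmost row
  g <- climate_grid(lons, lats_up, tmin,
                    array(rep(cell$tmax, each = 6), c(3, 2, 12)), arr,
                    array(rep(cell$rh09, each = 6), c(3, 2, 12)),
                    array(rep(cell$rh15, each = 6), c(3, 2, 12)))
  expect_equal(g$lats, c(14, 12, 10))
  expect_equal(g$tmin[3, 1, 1], cell$tmin[1] - 5)
})

test_that("climex_csv round trip is the identity on values and mask", {
  set.seed(3)
  cells <- replicate(6, random_cell(), simplify = FALSE)
  g <- grid_from_cells(cells)
  mask <- g$land_mask
  mask[1, 3] <- FALSE
  g <- climate_grid(g$lons, g$lats, g$tmin, g$tmax, g$precip, g$rh09,
                    g$rh15, land_mask = mask)
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_grid(g, path)
  g2 <- read_climate_grid(path, "climex_csv")
  expect_equal(g2$lons, g$lons)
  expect_equal(g2$lats, g$lats)
  expect_equal(g2$land_mask, g$land_mask)
  for (v in c("tmin", "tmax", "precip", "rh09", "rh15"))
    expect_equal(g2[[v]], g[[v]], tolerance = 1e-12)
})

test_that("climex_csv dialect matches a directly constructed grid", {
  set.seed(4)
  cells <- replicate(4, random_cell(), simplify = FALSE)
  g <- grid_from_cells(cells)
  # write the dialect by hand, independent of write_climate_grid
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- c("lon", "lat",
           sprintf("%s%02d", rep(c("tmin", "tmax", "prec", "rh09", "rh15"),
                                 each = 12), 1:12))
  rows <- vapply(seq_along(cells), function(i) {
    paste(c(g$lons[i], 40, cells[[i]]$tmin, cells[[i]]$tmax,
            cells[[i]]$precip, cells[[i]]$rh09, cells[[i]]$rh15),
          collapse = ",")
  }, character(1))
  writeLines(c(paste(hdr, collapse = ","), rows), path)
  g2 <- read_climate_grid(path)
  expect_equal(g2$tmin, g$tmin, tolerance = 1e-12)
  expect_equal(g2$precip, g$precip, tolerance = 1e-12)
})

test_that("read_climate_grid rejects missing columns and formats", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("lon,lat,tmin01\n0,0,5", path)
  expect_error(read_climate_grid(path), "missing column")
  expect_error(read_climate_grid(path, "netcdf"), "raster backend")
  expect_error(read_climate_grid("no/such/file.csv"), "not found")
})

test_that("raster round trip preserves values, mask and sentinel", {
  set.seed(5)
  g <- uniform_grid(random_cell(), nlat = 3, nlon = 4)
  layer <- matrix(rnorm(12), 3, 4)
  layer[2, 2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster(layer, g, path)
  back <- read_raster(path)
  expect_equal(back$layer, layer)
  # sentinel visible in the file itself
  raw <- data.table::fread(path)
  expect_true(any(raw$value == -9999))

  # all-masked layer -> full nodata
  write_raster(matrix(NA_real_, 3, 4), g, path)
  expect_true(all(is.na(read_raster(path)$layer)))

  expect_error(write_raster(matrix(0, 2, 2), g, path), "shape")
})

test_that("monthly_to_weekly preserves constants and conserves mass", {
  w <- monthly_to_weekly(rep(5, 12), rep(15, 12), rep(52, 12),
                         rep(0.7, 12), rep(0.5, 12))
  expect_equal(w$tmin_w, rep(5, 52))
  expect_equal(w$tavg_w, rep(10, 52))
  expect_equal(w$rh_w, rep(0.6, 52))
  expect_lt(max(abs(w$precip_w - 12)), 0.3)   # ~12 mm/week
  expect_equal(sum(w$precip_w), 624, tolerance = 0.005 / 100)

  # mass conservation and min/max envelope on random cells
  set.seed(6)
  for (i in 1:20) {
    cell <- random_cell()
    w <- monthly_to_weekly(cell$tmin, cell$tmax, cell$precip,
                           cell$rh09, cell$rh15)
    expect_equal(sum(w$precip_w), sum(cell$precip), tolerance = 1e-9)
    expect_gte(min(w$tmin_w), min(cell$tmin) - 1e-12)
    expect_lte(max(w$tmin_w), max(cell$tmin) + 1e-12)
    expect_gte(min(w$rh_w), min((cell$rh09 + cell$rh15) / 2) - 1e-12)
    expect_lte(max(w$rh_w), max((cell$rh09 + cell$rh15) / 2) + 1e-12)
  }
})

test_that("interpolation tracks a generating sinusoid within 0.2 degC", {
  doy_m <- ((1:12) - 0.5) * 364 / 12
  f <- function(t) 20 + 5 * sin(2 * pi * t / 364)
  w <- monthly_to_weekly(f(doy_m), f(doy_m) + 10, rep(50, 12),
                         rep(0.6, 12), rep(0.6, 12))
  wk <- 3.5 + 7 * (0:51)
  expect_lt(max(abs(w$tmin_w - f(wk))), 0.2)
})

test_that("monthly_to_weekly rejects bad input", {
  expect_error(monthly_to_weekly(rep(5, 11), rep(15, 12), rep(1, 12),
                                 rep(.5, 12), rep(.5, 12)), "12 finite")
  expect_error(monthly_to_weekly(c(NA, rep(5, 11)), rep(15, 12), rep(1, 12),
                                 rep(.5, 12), rep(.5, 12)), "finite")
})
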