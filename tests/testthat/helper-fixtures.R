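# Fixture builders used across test files. Everything is generated in code.

# random physically-valid monthly climate for one cell
random_cell <- function() {
  tavg <- runif(12, -10, 32)
  dr <- runif(1, 4, 14)
  list(tmin = tavg - dr / 2, tmax = tavg + dr / 2,
       precip = runif(12, 0, 250),
       rh09 = runif(12, 0.25, 0.95), rh15 = runif(12, 0.05, 0.85))
}

# small climate_grid filled with a single cell's climate everywhere
uniform_grid <- function(cell, nlat = 2, nlon = 2, res = 2) {
  lons <- seq(0 + res / 2, by = res, length.out = nlon)
  lats <- seq(30, by = -res, length.out = nlat)
  arr <- function(v) aperm(array(rep(v, each = nlat * nlon),
                                 c(nlat, nlon, 12)), c(1, 2, 3))
  climate_grid(lons, lats, arr(cell$tmin), arr(cell$tmax), arr(cell$precip),
               arr(cell$rh09), arr(cell$rh15))
}

# grid whose cells are drawn from a list of monthly cell climates
# (cells recycled down columns)
grid_from_cells <- function(cells, res = 2, lat0 = 40) {
  n <- length(cells)
  lons <- seq(res / 2, by = res, length.out = n)
  lats <- lat0
  build <- function(var) {
    a <- array(NA_real_, c(1, n, 12))
    for (i in seq_len(n)) a[1, i, ] <- cells[[i]][[var]]
    a
  }
  climate_grid(lons, lats, build("tmin"), build("tmax"), build("precip"),
               build("rh09"), build("rh15"))
}

# hand-built weekly series (bypasses interpolation) for unit formulas
weekly_series <- function(tmin = rep(19, 52), tmax = rep(29, 52),
                          precip = rep(20, 52), rh = rep(0.6, 52)) {
  structure(list(tmin_w = tmin, tmax_w = tmax, tavg_w = (tmin + tmax) / 2,
                 precip_w = precip, rh_w = rh),
            class = "weekly_series")
}

sm_trace <- function(sm) {
  structure(list(sm_w = sm, converged = TRUE, spinup_years = 1L),
            class = "soil_moisture_trace")
}
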