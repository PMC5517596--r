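#' Specification of a synthetic zonal world
#'
#' The generator emulates the structure of a global monthly climatology:
#' a latitudinal mean-temperature gradient, a seasonal cycle with opposite
#' phase in the two hemispheres (peak July in the north, January in the
#' south), a fixed diurnal range, and zonal precipitation regimes — wet
#' tropics (about 180 mm/month within 10 degrees of the equator), the
#' subtropical dry belts (about 15 mm/month at 15-35 degrees) and a
#' temperate regime poleward (about 70 mm/month). Relative humidity
#' co-varies with the precipitation zones and declines across the tropics
#' toward the dry belt, keeping the tropical water balance in slight
#' deficit everywhere (a flat humidity profile would flip the balance sign
#' within the tropics and peg soil moisture against a bound). Precipitation
#' carries a summer-peaking seasonal cycle so soil moisture traverses the
#' growth band instead of sitting at an equilibrium. Zonal profiles are
#' linear in |latitude| between the knots 0, 10, 15, 35, 40, 90 degrees.
#'
#' @param resolution Grid step, degrees (default 2).
#' @param t_eq Equatorial annual-mean temperature, degrees C (default 27).
#' @param lapse Latitudinal cooling, degrees C per degree latitude
#'   (default 0.55).
#' @param amp_coeff Seasonal amplitude, degrees C per degree latitude
#'   (default 0.35).
#' @param diurnal_range tmax - tmin, degrees C (default 10).
#' @param precip_zonal Mean precipitation at the zone knots, mm/month
#'   (tropics, dry belt, temperate; default 180, 15, 70).
#' @param precip_seasonality Relative amplitude of the summer-peaking
#'   precipitation cycle per zone (default 0.3, 0.3, 0.6).
#' @param rh_zonal Mean relative humidity at (equator, tropics edge,
#'   dry belt, temperate) (default 0.72, 0.65, 0.35, 0.60);
#'   rh09 = rh + 0.07, rh15 = rh - 0.07.
#' @param noise_sd_t,noise_sd_p Gaussian noise, degrees C on temperatures
#'   and mm/month on precipitation (defaults 0.3 and 2).
#' @param seed Integer seed making generation a pure function of the spec.
#' @return List of class `world_spec`.
#' @export
world_spec <- function(resolution = 2, t_eq = 27, lapse = 0.55,
                       amp_coeff = 0.35, diurnal_range = 10,
                       precip_zonal = c(tropics = 180, dry = 15,
                                        temperate = 70),
                       precip_seasonality = c(tropics = 0.3, dry = 0.3,
                                              temperate = 0.6),
                       rh_zonal = c(equator = 0.72, tropics_edge = 0.65,
                                    dry = 0.35, temperate = 0.60),
                       noise_sd_t = 0.3, noise_sd_p = 2, seed = 42L) {
  stopifnot(resolution > 0, diurnal_range >= 0, length(precip_zonal) == 3L,
            length(precip_seasonality) == 3L, length(rh_zonal) == 4L,
            noise_sd_t >= 0, noise_sd_p >= 0)
  structure(list(resolution = resolution, t_eq = t_eq, lapse = lapse,
                 amp_coeff = amp_coeff, diurnal_range = diurnal_range,
                 precip_zonal = unname(precip_zonal),
                 precip_seasonality = unname(precip_seasonality),
                 rh_zonal = unname(rh_zonal),
                 noise_sd_t = noise_sd_t, noise_sd_p = noise_sd_p,
                 seed = as.integer(seed)),
            class = "world_spec")
}

.zone_knots <- c(0, 10, 15, 35, 40, 90)

# zonal profile: per-zone values -> value at |phi|. Length-3 input is one
# value per zone (tropics, dry, temperate); length-4 additionally splits
# the tropics into equator / tropics-edge values (used for humidity).
.zonal_profile <- function(abs_lat, zone_values) {
  v <- if (length(zone_values) == 4L) zone_values[c(1, 2, 3, 3, 4, 4)]
       else zone_values[c(1, 1, 2, 2, 3, 3)]
  stats::approx(.zone_knots, v, abs_lat, rule = 2)$y
}

#' Generate a synthetic global monthly climatology
#'
#' Monthly mean temperature at latitude phi and month m is
#' `t_eq - lapse * |phi| + amp_coeff * |phi| * cos(2 pi (m - m_peak)/12)`
#' with `m_peak` July in the northern and January in the southern
#' hemisphere; `tmin`/`tmax` subtract/add half the diurnal range.
#' Precipitation and humidity follow the zonal profiles, with the
#' precipitation seasonal cycle peaking in the local summer. Seeded
#' Gaussian noise is added to temperatures and precipitation (precipitation
#' clamped at 0). Identical specs produce identical grids.
#'
#' @param spec A [world_spec].
#' @param land_mask Optional logical mask; default all-land (see
#'   [toy_continents] for a simple partition for regional tables).
#' @return A [climate_grid].
#' @export
generate_world <- function(spec = world_spec(), land_mask = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  res <- spec$resolution
  lons <- seq(-180 + res / 2, 180 - res / 2, by = res)
  lats <- seq(90 - res / 2, -90 + res / 2, by = -res)
  nlat <- length(lats); nlon <- length(lons)

  abs_lat <- abs(lats)
  m_peak <- ifelse(lats >= 0, 7, 1)       # July north, January south
  months <- 1:12

  tavg_lat <- outer(lats, months, function(phi, m)
    spec$t_eq - spec$lapse * abs(phi) +
      spec$amp_coeff * abs(phi) *
        cos(2 * pi * (m - ifelse(phi >= 0, 7, 1)) / 12))
  p_mean <- .zonal_profile(abs_lat, spec$precip_zonal)
  p_seas <- .zonal_profile(abs_lat, spec$precip_seasonality)
  prec_lat <- outer(seq_along(lats), months, function(i, m)
    p_mean[i] * (1 + p_seas[i] * cos(2 * pi * (m - m_peak[i]) / 12)))
  rh_lat <- .zonal_profile(abs_lat, spec$rh_zonal)

  expand <- function(lat_month) {          # nlat x 12 -> nlat x nlon x 12
    aperm(array(rep(lat_month, times = nlon), c(nlat, 12, nlon)), c(1, 3, 2))
  }
  tavg <- expand(tavg_lat)
  prec <- expand(prec_lat)
  rh09 <- expand(matrix(pmin(rh_lat + 0.07, 1), nlat, 12))
  rh15 <- expand(matrix(pmax(rh_lat - 0.07, 0), nlat, 12))

  set.seed(spec$seed)
  dims <- c(nlat, nlon, 12)
  tavg <- tavg + array(stats::rnorm(prod(dims), 0, spec$noise_sd_t), dims)
  prec <- pmax(prec + array(stats::rnorm(prod(dims), 0, spec$noise_sd_p),
                            dims), 0)
  tmin <- tavg - spec$diurnal_range / 2
  tmax <- tavg + spec$diurnal_range / 2

  climate_grid(lons, lats, tmin, tmax, prec, rh09, rh15,
               land_mask = land_mask)
}

#' GCM-like scenario perturbation
#'
#' @param dt_uniform Uniform warming, degrees C (default 0; the headline
#'   end-of-century magnitude under a high-emission scenario is 3.4).
#' @param dt_polar_amplification Extra warming per degree latitude
#'   (default 0).
#' @param precip_scale Multiplicative precipitation factor: a single
#'   scalar, or a length-3 vector applied per zone (tropics, dry belt,
#'   temperate) through the same zonal blending as the generator.
#' @param label Scenario name.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(dt_uniform = 0, dt_polar_amplification = 0,
                          precip_scale = 1, label = "scenario") {
  stopifnot(is.numeric(dt_uniform), is.numeric(dt_polar_amplification),
            length(precip_scale) %in% c(1L, 3L))
  structure(list(dt_uniform = dt_uniform,
                 dt_polar_amplification = dt_polar_amplification,
                 precip_scale = unname(precip_scale), label = label),
            class = "scenario_spec")
}

#' Apply a scenario perturbation to a climatology
#'
#' Temperatures are shifted by `dt_uniform + dt_polar_amplification * |phi|`;
#' precipitation is scaled (clamped at 0 with a warning if a negative
#' factor would produce negative totals); humidity is unchanged. The
#' identity scenario returns the input unchanged.
#'
#' @param grid A [climate_grid].
#' @param s A [scenario_spec].
#' @return A perturbed [climate_grid].
#' @export
apply_scenario <- function(grid, s) {
  stopifnot(inherits(grid, "climate_grid"), inherits(s, "scenario_spec"))
  identity_s <- s$dt_uniform == 0 && s$dt_polar_amplification == 0 &&
    all(s$precip_scale == 1)
  if (identity_s) return(grid)

  nlat <- length(grid$lats); nlon <- length(grid$lons)
  dt_lat <- s$dt_uniform + s$dt_polar_amplification * abs(grid$lats)
  dt_arr <- array(rep(dt_lat, times = nlon * 12), c(nlat, nlon, 12))

  scale_lat <- if (length(s$precip_scale) == 1L) rep(s$precip_scale, nlat)
               else .zonal_profile(abs(grid$lats), s$precip_scale)
  sc_arr <- array(rep(scale_lat, times = nlon * 12), c(nlat, nlon, 12))
  prec <- grid$precip * sc_arr
  if (any(prec < 0, na.rm = TRUE)) {
    warning("negative scaled precipitation clamped at 0")
    prec <- pmax(prec, 0)
  }
  climate_grid(grid$lons, grid$lats,
               grid$tmin + dt_arr, grid$tmax + dt_arr, prec,
               grid$rh09, grid$rh15, land_mask = grid$land_mask)
}

#' Sample synthetic occurrence records from a suitability surface
#'
#' Draws `round((1 - contamination) * n)` points uniformly from cells with
#' `EI >= suitable_min` and the remainder from unsuitable land cells,
#' jittered uniformly within the cell. Emulates the structure of a large
#' presence compilation in which a few percent of records fall outside the
#' modelled suitable range.
#'
#' @param result An `ei_grid` from [run_grid] (or a list with `ei` matrix
#'   and `grid`).
#' @param n Number of records.
#' @param suitable_min EI threshold separating suitable from unsuitable
#'   (default 1).
#' @param contamination Fraction drawn from unsuitable cells (default 0.04).
#' @param seed Integer seed.
#' @return `data.frame` with columns `lon`, `lat`.
#' @export
sample_occurrences <- function(result, n, suitable_min = 1,
                               contamination = 0.04, seed = 1L) {
  ei <- result$ei
  grid <- result$grid
  res <- grid$resolution
  land <- which(grid$land_mask & !is.na(ei))
  good <- land[ei[land] >= suitable_min]
  bad <- land[ei[land] < suitable_min]
  if (length(good) == 0L) stop("no suitable cells to sample from")
  n_bad <- round(contamination * n)
  if (n_bad > 0 && length(bad) == 0L)
    stop("contamination requested but no unsuitable cells exist")
  n_good <- n - n_bad

  set.seed(as.integer(seed))
  cells <- c(sample(good, n_good, replace = TRUE),
             if (n_bad > 0) sample(bad, n_bad, replace = TRUE))
  ri <- (cells - 1L) %% nrow(ei) + 1L
  ci <- (cells - 1L) %/% nrow(ei) + 1L
  jit_lon <- stats::runif(n, -res / 2, res / 2)
  jit_lat <- stats::runif(n, -res / 2, res / 2)
  data.frame(lon = grid$lons[ci] + jit_lon,
             lat = grid$lats[ri] + jit_lat)
}

#' Toy continental partition for regional tables
#'
#' Splits the grid into named longitude-hemisphere blocks ("west"/"east"
#' crossed with "north"/"tropics"/"south") purely for exercising the
#' regional change accounting; the blocks are pairwise disjoint and cover
#' every cell.
#'
#' @param grid A [climate_grid].
#' @return Named list of [region_mask] objects.
#' @export
toy_continents <- function(grid) {
  lonm <- matrix(rep(grid$lons, each = length(grid$lats)),
                 length(grid$lats), length(grid$lons))
  latm <- matrix(rep(grid$lats, times = length(grid$lons)),
                 length(grid$lats), length(grid$lons))
  west <- lonm < 0
  bands <- list(north = latm > 23.5, tropics = abs(latm) <= 23.5,
                south = latm < -23.5)
  out <- list()
  for (ew in c("west", "east")) {
    for (b in names(bands)) {
      nm <- paste(ew, b, sep = "_")
      out[[nm]] <- region_mask(nm, (if (ew == "west") west else !west) &
                                 bands[[b]])
    }
  }
  out
}
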