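#' Hydrology configuration
#'
#' Constants of the weekly soil-moisture bucket. The bucket expresses soil
#' water as a fraction of the soil-moisture holding capacity; the fraction
#' may exceed 1 (waterlogging) up to `sm_cap`, which is what makes the
#' limiting high soil moisture SM3 = 1.3 and the wet-stress threshold
#' reachable.
#'
#' @param capacity_mm Soil-moisture holding capacity (mm), default 100.
#' @param sm_cap Ceiling on the soil-moisture fraction, default 2.0.
#' @param e_coeff Evapotranspiration coefficient (mm per degree C per day),
#'   default 0.8.
#' @param tol Convergence tolerance on the 52-week trace between consecutive
#'   spin-up years, default 1e-6.
#' @param max_years Spin-up limit, default 50.
#' @param sm0 Initial soil-moisture fraction, default 0.5.
#' @return List of class `hydro_config`.
#' @export
hydro_config <- function(capacity_mm = 100, sm_cap = 2.0, e_coeff = 0.8,
                         tol = 1e-6, max_years = 50L, sm0 = 0.5) {
  stopifnot(capacity_mm > 0, sm_cap > 0, e_coeff >= 0, tol > 0,
            max_years >= 1, sm0 >= 0, sm0 <= sm_cap)
  structure(list(capacity_mm = capacity_mm, sm_cap = sm_cap,
                 e_coeff = e_coeff, tol = tol,
                 max_years = as.integer(max_years), sm0 = sm0),
            class = "hydro_config")
}

#' Weekly evapotranspiration demand
#'
#' A minimal humidity-deficit formulation:
#' `E = e_coeff * max(tavg, 0) * (1 - rh) * 7` mm/week. Frozen weeks
#' (`tavg <= 0`) and saturated air (`rh = 1`) evaporate nothing.
#'
#' @param tavg_w Weekly mean temperature(s), degrees C.
#' @param rh_w Weekly relative humidity, fraction.
#' @param e_coeff mm per degree C per day, default 0.8.
#' @return Evapotranspiration in mm/week, same shape as the inputs.
#' @export
weekly_evapotranspiration <- function(tavg_w, rh_w, e_coeff = 0.8) {
  if (!all(is.finite(tavg_w)) || !all(is.finite(rh_w)))
    stop("non-finite input to weekly_evapotranspiration")
  e_coeff * pmax(tavg_w, 0) * (1 - rh_w) * 7
}

# Core recursion on matrices (ncell x 52). Iterates whole annual cycles
# from a common initial fraction until the trace is stationary.
.bucket_matrix <- function(precip_w, et_w, capacity_mm = 100, sm_cap = 2.0,
                           tol = 1e-6, max_years = 50L, sm0 = 0.5) {
  ncell <- nrow(precip_w)
  net <- (precip_w - et_w) / capacity_mm
  sm <- matrix(NA_real_, ncell, 52)
  prev <- matrix(Inf, ncell, 52)
  state <- rep(sm0, ncell)
  converged <- FALSE
  years <- 0L
  for (y in seq_len(max_years)) {
    years <- y
    for (w in 1:52) {
      state <- pmin(pmax(state + net[, w], 0), sm_cap)
      sm[, w] <- state
    }
    if (max(abs(sm - prev)) < tol) { converged <- TRUE; break }
    prev[] <- sm
  }
  list(sm_w = sm, converged = converged, spinup_years = years)
}

#' Run the weekly soil-moisture bucket for one cell
#'
#' The recursion
#' `sm[w] = clamp(sm[w-1] + (P[w] - E[w]) / capacity_mm, 0, sm_cap)`
#' is iterated over repeated annual cycles from `sm0` until the 52-week
#' trace changes by less than `tol` between consecutive years. The converged
#' trace is independent of `sm0` (the map is monotone and contracting onto
#' its attractor); non-convergence within `max_years` returns the last
#' trace with `converged = FALSE` and a warning.
#'
#' @param weekly A `weekly_series` from [monthly_to_weekly].
#' @param config A [hydro_config].
#' @return A `soil_moisture_trace`: list with `sm_w` (52 soil-moisture
#'   fractions), `converged`, `spinup_years`.
#' @export
run_bucket <- function(weekly, config = hydro_config()) {
  stopifnot(inherits(weekly, "weekly_series"))
  et <- weekly_evapotranspiration(weekly$tavg_w, weekly$rh_w, config$e_coeff)
  res <- .bucket_matrix(matrix(weekly$precip_w, 1), matrix(et, 1),
                        capacity_mm = config$capacity_mm,
                        sm_cap = config$sm_cap, tol = config$tol,
                        max_years = config$max_years, sm0 = config$sm0)
  if (!res$converged)
    warning(sprintf("soil-moisture bucket not converged after %d years",
                    res$spinup_years))
  structure(list(sm_w = as.vector(res$sm_w), converged = res$converged,
                 spinup_years = res$spinup_years),
            class = "soil_moisture_trace")
}
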