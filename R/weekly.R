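#' @name weekly
#' @title Monthly to weekly disaggregation
#'
#' @description
#' The model integrates growth and stress on a weekly time step, but the
#' climatology is monthly. The model year has 364 days (52 weeks of 7 days,
#' 12 months of 364/12 days). State variables (temperature, humidity) are
#' anchored at mid-month day-of-year and linearly interpolated, with cyclic
#' wrap, to week midpoints (day 3.5 + 7k). Precipitation is a flux:
#' each month's total is spread uniformly over its days and weekly totals
#' are the 7-day sums, which conserves the annual total exactly.
#'
#' Both maps are linear, so they are precomputed once as 52 x 12 matrices.
NULL

.days_per_month <- 364 / 12

# 52 x 12 cyclic linear interpolation matrix (state variables)
.weekly_state_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mm <- ((1:12) - 0.5) * .days_per_month     # month midpoints
    wk <- 3.5 + 7 * (0:51)                     # week midpoints
    W <- matrix(0, 52, 12)
    for (i in 1:52) {
      t <- wk[i]
      j <- findInterval(t, mm)
      if (j == 0L) { j <- 12L; t <- t + 364 }  # wrap before mid-January
      jn <- if (j == 12L) 1L else j + 1L
      x1 <- mm[j]
      x2 <- if (j == 12L) mm[1] + 364 else mm[jn]
      w <- (t - x1) / (x2 - x1)
      W[i, j] <- W[i, j] + (1 - w)
      W[i, jn] <- W[i, jn] + w
    }
    cache <<- W
    W
  }
})

# 52 x 12 mass-conserving precipitation matrix
.weekly_flux_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    day_month <- floor(((0:363) + 0.5) / .days_per_month) + 1  # month of day
    month_len <- tabulate(day_month, nbins = 12)  # 30/31-day integer months
    W <- matrix(0, 52, 12)
    for (k in 1:52) {
      days <- ((k - 1) * 7 + 1):(k * 7)
      tab <- tabulate(day_month[days], nbins = 12)
      W[k, ] <- tab / month_len  # column sums are exactly 1: mass conserved
    }
    cache <<- W
    W
  }
})

#' Disaggregate one cell's monthly climate to 52 weeks
#'
#' @param tmin,tmax Monthly average minimum / maximum temperature (12 values,
#'   degrees C).
#' @param precip Monthly total precipitation (12 values, mm/month).
#' @param rh09,rh15 Monthly relative humidity at 09:00 / 15:00 (12 values,
#'   fractions). The model humidity is their mean.
#' @return A `weekly_series`: list with `tmin_w`, `tmax_w`, `tavg_w`
#'   (degrees C), `precip_w` (mm/week) and `rh_w` (fraction), 52 values each.
#'   The annual precipitation total is conserved exactly.
#' @export
monthly_to_weekly <- function(tmin, tmax, precip, rh09, rh15) {
  vars <- list(tmin = tmin, tmax = tmax, precip = precip,
               rh09 = rh09, rh15 = rh15)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (length(v) != 12L || !all(is.finite(v)))
      stop(sprintf("'%s' must be 12 finite values", nm))
  }
  S <- .weekly_state_matrix()
  Fx <- .weekly_flux_matrix()
  out <- list(
    tmin_w = as.vector(S %*% tmin),
    tmax_w = as.vector(S %*% tmax),
    precip_w = as.vector(Fx %*% precip),
    rh_w = as.vector(S %*% ((rh09 + rh15) / 2)))
  out$tavg_w <- (out$tmin_w + out$tmax_w) / 2
  structure(out, class = "weekly_series")
}

# Vectorized form: monthly matrices (ncell x 12) -> weekly matrices
# (ncell x 52). Used by the grid runner; the scalar monthly_to_weekly()
# is the reference path.
.weekly_matrices <- function(tmin_m, tmax_m, precip_m, rh_m) {
  S <- t(.weekly_state_matrix())
  Fx <- t(.weekly_flux_matrix())
  tmin_w <- tmin_m %*% S
  tmax_w <- tmax_m %*% S
  list(tmin_w = tmin_w, tmax_w = tmax_w,
       tavg_w = (tmin_w + tmax_w) / 2,
       precip_w = precip_m %*% Fx,
       rh_w = rh_m %*% S)
}
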