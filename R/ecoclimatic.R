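#' Trapezoidal response function
#'
#' Piecewise-linear suitability in \[0, 1\]: 0 at or below `a` and at or
#' above `d`, rising linearly on (a, b), 1 on \[b, c\], falling on (c, d).
#' This is the shape of both the temperature index (DV0..DV3) and the
#' moisture index (SM0..SM3).
#'
#' @param x Value(s) to evaluate.
#' @param a,b,c,d Breakpoints with `a < b <= c < d`.
#' @return Values in \[0, 1\], same shape as `x`.
#' @export
trapezoid <- function(x, a, b, c, d) {
  if (!(a < b && b <= c && c < d))
    stop("trapezoid breakpoints must satisfy a < b <= c < d")
  out <- numeric(length(x))
  out[x > a & x < b] <- (x[x > a & x < b] - a) / (b - a)
  out[x >= b & x <= c] <- 1
  out[x > c & x < d] <- (d - x[x > c & x < d]) / (d - c)
  dim(out) <- dim(x)
  out
}

#' Weekly temperature index
#'
#' TI is the trapezoid DV0..DV3 evaluated on the weekly mean temperature:
#' zero outside the survivable range, 1 across the optimal plateau
#' DV1..DV2.
#'
#' @param weekly A `weekly_series`.
#' @param p A [maize_parameters].
#' @return 52 weekly TI values in \[0, 1\].
#' @export
temperature_index <- function(weekly, p = maize_parameters()) {
  stopifnot(inherits(weekly, "weekly_series"))
  trapezoid(weekly$tavg_w, p$dv0, p$dv1, p$dv2, p$dv3)
}

#' Weekly moisture index
#'
#' MI is the trapezoid SM0..SM3 evaluated on the weekly soil-moisture
#' fraction from the bucket model.
#'
#' @param sm A `soil_moisture_trace` (a warning is given if it did not
#'   converge) or a plain numeric vector of 52 fractions.
#' @param p A [maize_parameters].
#' @return 52 weekly MI values in \[0, 1\].
#' @export
moisture_index <- function(sm, p = maize_parameters()) {
  if (inherits(sm, "soil_moisture_trace")) {
    if (!isTRUE(sm$converged))
      warning("moisture index computed from a non-converged soil-moisture trace")
    sm <- sm$sm_w
  }
  trapezoid(sm, p$sm0, p$sm1, p$sm2, p$sm3)
}

#' Annual growth index
#'
#' GI_A = 100 * mean over 52 weeks of TI * MI: the fraction of an ideal
#' growth year actually realised.
#'
#' @param ti_w,mi_w 52 weekly index values each.
#' @return Scalar in \[0, 100\].
#' @export
annual_growth_index <- function(ti_w, mi_w) {
  stopifnot(length(ti_w) == 52L, length(mi_w) == 52L)
  100 * sum(ti_w * mi_w) / 52
}

# Consecutive-stress-week counts with wrap across the year boundary.
# Two passes over the 52 weeks: the second pass carries the run length
# across week 52 -> week 1. If every week is stressed the counts are
# 53..104 (a year already under way), capping the compounding.
.stress_counts <- function(stressed) {
  cc <- matrix(0, nrow(stressed), 52)
  run <- numeric(nrow(stressed))
  for (pass in 1:2) {
    for (w in 1:52) {
      run <- ifelse(stressed[, w], run + 1, 0)
      cc[, w] <- run
    }
  }
  cc
}

# Matrix form of accumulate_stress: values (ncell x 52) -> stress per cell.
.stress_matrix <- function(values, threshold, rate,
                           side = c("below", "above"),
                           accumulation = c("compound", "linear")) {
  side <- match.arg(side)
  accumulation <- match.arg(accumulation)
  D <- if (side == "below") threshold - values else values - threshold
  D[D < 0] <- 0
  weight <- if (accumulation == "compound") .stress_counts(D > 0) else (D > 0) * 1
  pmin(100, 100 * abs(rate) * rowSums(D * weight))
}

#' Accumulate a weekly stress index
#'
#' Weeks on the stressful side of the threshold contribute
#' `|rate| * exceedance * c_w`, where `c_w` counts consecutive stress weeks
#' ending at week w (wrapping across the year boundary), so sustained
#' stress accumulates at an accelerating pace; the sum is scaled by 100 and
#' capped at 100, at which point persistence is excluded. Set
#' `accumulation = "linear"` for the non-compounding variant (`c_w = 1`).
#'
#' @param values_w 52 weekly driver values (e.g. tmin, tmax, soil moisture).
#' @param threshold Stress threshold.
#' @param rate Weekly accumulation rate; only its magnitude is used.
#' @param side `"below"` (cold, dry) or `"above"` (heat, wet).
#' @param accumulation `"compound"` (default) or `"linear"`.
#' @return Stress index in \[0, 100\].
#' @export
accumulate_stress <- function(values_w, threshold, rate,
                              side = c("below", "above"),
                              accumulation = c("compound", "linear")) {
  stopifnot(length(values_w) == 52L, is.finite(threshold))
  .stress_matrix(matrix(values_w, 1), threshold, rate,
                 match.arg(side), match.arg(accumulation))
}

#' Suitability category of an Ecoclimatic Index value
#'
#' EI = 0 is unsuitable; 0 < EI <= 10 marginal; 10 < EI <= 20 medium
#' (large populations can persist); EI > 20 optimal. Bins are left-open /
#' right-closed; values in (0, 1), which the published bins leave
#' unassigned, are classed marginal.
#'
#' @param ei Numeric EI values in \[0, 100\] (NA allowed, kept NA).
#' @return Factor with levels unsuitable, marginal, medium, optimal.
#' @export
classify_ei <- function(ei) {
  ok <- is.na(ei) | (ei >= 0 & ei <= 100)
  if (!all(ok)) stop("EI values must lie in [0, 100]")
  out <- ifelse(is.na(ei), NA_character_,
         ifelse(ei == 0, "unsuitable",
         ifelse(ei <= 10, "marginal",
         ifelse(ei <= 20, "medium", "optimal"))))
  factor(out, levels = .ei_categories)
}

.ei_categories <- c("unsuitable", "marginal", "medium", "optimal")

#' Ecoclimatic Index for one cell
#'
#' Combines the annual growth index with the four stress indices:
#' `EI = GI_A * (1 - CS/100)(1 - DS/100)(1 - HS/100)(1 - WS/100)`.
#' Cold stress is driven by weekly minimum temperature below TTCS, heat
#' stress by weekly maximum temperature above TTHS, dry and wet stress by
#' the soil-moisture fraction below SMDS / above SMWS. Any stress of 100
#' forces EI = 0 (unsuitable); EI never exceeds GI_A.
#'
#' @param weekly A `weekly_series`.
#' @param sm A `soil_moisture_trace` for the same cell.
#' @param p A [maize_parameters].
#' @param accumulation Stress accumulation variant, see [accumulate_stress].
#' @return An `ei_result`: list with `ti_w`, `mi_w` (52 values each),
#'   `gi_a`, `cs`, `hs`, `ds`, `ws`, `ei` (all in \[0, 100\]) and
#'   `category`.
#' @export
compute_ei <- function(weekly, sm, p = maize_parameters(),
                       accumulation = c("compound", "linear")) {
  accumulation <- match.arg(accumulation)
  stopifnot(inherits(weekly, "weekly_series"))
  ti <- temperature_index(weekly, p)
  mi <- moisture_index(sm, p)
  sm_w <- if (inherits(sm, "soil_moisture_trace")) sm$sm_w else sm
  gi <- annual_growth_index(ti, mi)
  cs <- accumulate_stress(weekly$tmin_w, p$ttcs, p$thcs, "below", accumulation)
  hs <- accumulate_stress(weekly$tmax_w, p$tths, p$thhs, "above", accumulation)
  ds <- accumulate_stress(sm_w, p$smds, p$hds, "below", accumulation)
  ws <- accumulate_stress(sm_w, p$smws, p$hws, "above", accumulation)
  ei <- gi * (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)
  ei <- min(max(ei, 0), 100)  # guard FP overshoot of the closed bounds
  structure(list(ti_w = ti, mi_w = mi, gi_a = gi,
                 cs = cs, hs = hs, ds = ds, ws = ws, ei = ei,
                 category = classify_ei(ei)),
            class = "ei_result")
}

# Assemble weekly matrices + converged soil moisture for all land cells.
# Returned matrices are (n_land x 52); `cells` holds the linear indices of
# the land cells in the nlat x nlon grid. Reused across parameter sets by
# the sensitivity analysis (the bucket does not depend on the species
# parameters).
prepare_grid <- function(grid, hydro = hydro_config()) {
  stopifnot(inherits(grid, "climate_grid"))
  cells <- which(grid$land_mask)
  n <- length(cells)
  pick <- function(a) {
    m <- matrix(NA_real_, n, 12)
    for (mo in 1:12) m[, mo] <- a[, , mo][cells]
    m
  }
  wk <- .weekly_matrices(pick(grid$tmin), pick(grid$tmax), pick(grid$precip),
                         (pick(grid$rh09) + pick(grid$rh15)) / 2)
  et <- weekly_evapotranspiration(wk$tavg_w, wk$rh_w, hydro$e_coeff)
  bucket <- .bucket_matrix(wk$precip_w, et,
                           capacity_mm = hydro$capacity_mm,
                           sm_cap = hydro$sm_cap, tol = hydro$tol,
                           max_years = hydro$max_years, sm0 = hydro$sm0)
  if (!bucket$converged)
    warning("soil-moisture bucket not converged on some cells")
  list(cells = cells, dims = dim(grid), weekly = wk, sm_w = bucket$sm_w,
       converged = bucket$converged, grid = grid)
}

#' Run the ecoclimatic model over a grid
#'
#' Evaluates [compute_ei] on every land cell of a [climate_grid] (in
#' vectorized form) and returns aligned raster layers. Masked cells carry
#' `NA`. The computation is deterministic.
#'
#' @param grid A [climate_grid].
#' @param p A [maize_parameters].
#' @param hydro A [hydro_config].
#' @param accumulation Stress accumulation variant, see [accumulate_stress].
#' @param prepared Optional precomputed weekly/soil-moisture state from a
#'   previous run on the same grid and hydrology (used internally by the
#'   sensitivity analysis).
#' @return An `ei_grid`: list with matrices `ei`, `gi_a`, `cs`, `hs`, `ds`,
#'   `ws` (`nlat x nlon`), a factor-valued `category` matrix, and the
#'   originating `grid`.
#' @export
run_grid <- function(grid, p = maize_parameters(), hydro = hydro_config(),
                     accumulation = c("compound", "linear"),
                     prepared = NULL) {
  accumulation <- match.arg(accumulation)
  if (is.null(prepared)) prepared <- prepare_grid(grid, hydro)
  wk <- prepared$weekly
  sm <- prepared$sm_w
  ti <- trapezoid(wk$tavg_w, p$dv0, p$dv1, p$dv2, p$dv3)
  mi <- trapezoid(sm, p$sm0, p$sm1, p$sm2, p$sm3)
  gi <- 100 * rowSums(ti * mi) / 52
  cs <- .stress_matrix(wk$tmin_w, p$ttcs, p$thcs, "below", accumulation)
  hs <- .stress_matrix(wk$tmax_w, p$tths, p$thhs, "above", accumulation)
  ds <- .stress_matrix(sm, p$smds, p$hds, "below", accumulation)
  ws <- .stress_matrix(sm, p$smws, p$hws, "above", accumulation)
  ei <- gi * (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)
  ei <- pmin(pmax(ei, 0), 100)

  lay <- function(v) {
    m <- matrix(NA_real_, prepared$dims[1], prepared$dims[2])
    m[prepared$cells] <- v
    m
  }
  ei_m <- lay(ei)
  cat_codes <- matrix(NA_integer_, prepared$dims[1], prepared$dims[2])
  cat_codes[prepared$cells] <- as.integer(classify_ei(ei))
  category <- structure(cat_codes, levels = .ei_categories,
                        class = c("matrix", "array"))
  structure(list(ei = ei_m, gi_a = lay(gi), cs = lay(cs), hs = lay(hs),
                 ds = lay(ds), ws = lay(ws), category = category,
                 grid = grid, parameters = p),
            class = "ei_grid")
}

#' @export
print.ei_grid <- function(x, ...) {
  counts <- category_counts(x)
  cat(sprintf("<ei_grid> %d x %d cells; EI in [%.2f, %.2f]\n",
              nrow(x$ei), ncol(x$ei),
              min(x$ei, na.rm = TRUE), max(x$ei, na.rm = TRUE)))
  print(counts)
  invisible(x)
}

#' Category layer of an `ei_grid` as a factor matrix helper
#'
#' @param result An `ei_grid` from [run_grid].
#' @return Named integer vector of cell counts per suitability category.
#' @export
category_counts <- function(result) {
  stopifnot(inherits(result, "ei_grid"))
  codes <- factor(.ei_categories[as.vector(result$category)],
                  levels = .ei_categories)
  table(codes, dnn = NULL)
}
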