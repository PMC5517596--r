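#' Default one-at-a-time perturbation steps
#'
#' Temperature thresholds (DV0..DV3, TTCS, TTHS): +/- 1 degree C, absolute.
#' Moisture thresholds (SM0..SM3, SMDS, SMWS): +/- 0.1, absolute. Stress
#' rates (THCS, THHS, HDS, HWS): +/- 10%, relative (magnitude-scaled).
#'
#' @return `data.frame` with columns `parameter`, `delta`, `mode`, two rows
#'   (low/high) per parameter.
#' @export
default_sensitivity_steps <- function() {
  temp <- c("dv0", "dv1", "dv2", "dv3", "ttcs", "tths")
  moist <- c("sm0", "sm1", "sm2", "sm3", "smds", "smws")
  rates <- c("thcs", "thhs", "hds", "hws")
  rbind(
    data.frame(parameter = rep(temp, each = 2),
               delta = rep(c(-1, 1), length(temp)), mode = "absolute"),
    data.frame(parameter = rep(moist, each = 2),
               delta = rep(c(-0.1, 0.1), length(moist)), mode = "absolute"),
    data.frame(parameter = rep(rates, each = 2),
               delta = rep(c(-0.1, 0.1), length(rates)), mode = "relative"))
}

# area (km^2) with EI >= suitable_min for one run
.suitable_area <- function(result, areas, suitable_min = 1) {
  sel <- !is.na(result$ei) & result$ei >= suitable_min
  sum(areas[sel])
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Re-runs the model with each parameter perturbed in turn (the weekly
#' climate and soil-moisture state are computed once and reused — the
#' hydrology does not depend on the species parameters), measures the
#' suitable area (EI >= `suitable_min`) and reports the range change
#' `100 * |A_perturbed - A_base| / A_base` per step. Parameters are ranked
#' by their maximum range change (ties broken by name, so the order is
#' stable) and labelled `"sensitive"` above the cutoff, `"insensitive"`
#' otherwise. Perturbations that would violate the parameter ordering are
#' recorded with `NA` change.
#'
#' @param grid A [climate_grid].
#' @param p Baseline [maize_parameters].
#' @param steps Perturbation table as from [default_sensitivity_steps].
#' @param hydro A [hydro_config].
#' @param suitable_min EI threshold defining the suitable range (default 1).
#' @param cutoff Range-change percentage separating sensitive from
#'   insensitive (default 2).
#' @param accumulation Stress accumulation variant, see [accumulate_stress].
#' @return A `sensitivity_report`: list with `steps` (per-step results),
#'   `summary` (per-parameter max change, rank, label), `baseline_area_km2`
#'   and the settings used.
#' @export
run_sensitivity <- function(grid, p = maize_parameters(),
                            steps = default_sensitivity_steps(),
                            hydro = hydro_config(), suitable_min = 1,
                            cutoff = 2,
                            accumulation = c("compound", "linear")) {
  accumulation <- match.arg(accumulation)
  stopifnot(is.data.frame(steps),
            all(c("parameter", "delta", "mode") %in% names(steps)))
  prepared <- prepare_grid(grid, hydro)
  areas <- cell_areas(grid$lats, grid$lons, grid$resolution)
  base <- run_grid(grid, p, hydro, accumulation, prepared = prepared)
  a_base <- .suitable_area(base, areas, suitable_min)
  if (a_base <= 0) stop("baseline suitable area is zero")

  res <- steps
  res$area_km2 <- NA_real_
  res$range_change_pct <- NA_real_
  for (i in seq_len(nrow(steps))) {
    q <- try(perturb_parameter(p, steps$parameter[i], steps$delta[i],
                               steps$mode[i]), silent = TRUE)
    if (inherits(q, "try-error")) next
    r <- run_grid(grid, q, hydro, accumulation, prepared = prepared)
    a <- .suitable_area(r, areas, suitable_min)
    res$area_km2[i] <- a
    res$range_change_pct[i] <- 100 * abs(a - a_base) / a_base
  }

  params <- sort(unique(res$parameter))
  max_change <- vapply(params, function(nm) {
    v <- res$range_change_pct[res$parameter == nm]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-ifelse(is.na(max_change), -Inf, max_change), params)
  summary <- data.frame(parameter = params[ord],
                        max_range_change_pct = max_change[ord],
                        rank = seq_along(params))
  summary$label <- ifelse(is.na(summary$max_range_change_pct), "insensitive",
                          ifelse(summary$max_range_change_pct > cutoff,
                                 "sensitive", "insensitive"))
  structure(list(steps = res, summary = summary,
                 baseline_area_km2 = a_base, suitable_min = suitable_min,
                 cutoff = cutoff),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> baseline suitable area %.3g km^2, cutoff %g%%\n",
              x$baseline_area_km2, x$cutoff))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity report to CSV
#'
#' @param report A `sensitivity_report`.
#' @param path Output CSV (per-step rows: parameter, delta, mode, area,
#'   range change).
#' @export
write_sensitivity <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  utils::write.csv(report$steps, path, row.names = FALSE)
  invisible(path)
}
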