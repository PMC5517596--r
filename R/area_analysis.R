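#' Region mask
#'
#' A named boolean layer aligned to the grid, marking member cells of a
#' region (continent, country, latitude band, ...).
#'
#' @param name Region name.
#' @param mask Logical `nlat x nlon` matrix.
#' @return List of class `region_mask`.
#' @export
region_mask <- function(name, mask) {
  stopifnot(is.character(name), length(name) == 1L,
            is.logical(mask), is.matrix(mask))
  structure(list(name = name, mask = mask), class = "region_mask")
}

.earth_radius_km <- 6371

#' Spherical cell areas of a regular lon/lat grid
#'
#' Exact spherical band areas:
#' `area(phi) = R^2 * dlambda * (sin(phi + d/2) - sin(phi - d/2))` with
#' R = 6371 km. Summed over a full global grid this telescopes to
#' `4 pi R^2`, so category shares computed with these weights are exactly
#' the equal-area (Behrmann-projected) shares.
#'
#' @param lats Cell-centre latitudes (degrees).
#' @param lons Cell-centre longitudes (degrees).
#' @param resolution Grid step (degrees).
#' @return Matrix `length(lats) x length(lons)` of areas in km^2.
#' @export
cell_areas <- function(lats, lons, resolution) {
  d <- resolution * pi / 180
  phi <- lats * pi / 180
  band <- .earth_radius_km^2 * d *
    (sin(pmin(phi + d / 2, pi / 2)) - sin(pmax(phi - d / 2, -pi / 2)))
  matrix(rep(band, times = length(lons)), length(lats), length(lons))
}

# category codes (integer 1..4 or factor-coded matrix) -> integer matrix
.category_codes <- function(category_layer) {
  m <- category_layer
  attributes(m) <- list(dim = dim(category_layer))
  storage.mode(m) <- "integer"
  m
}

#' Area-weighted suitability summary of one region
#'
#' @param category_layer Category matrix from [run_grid] (`$category`).
#' @param areas Cell-area matrix from [cell_areas].
#' @param mask A [region_mask].
#' @param ei_gt_1 If `TRUE`, "suitable" excludes the marginal sliver with
#'   EI in (0, 1\]; requires `ei_layer`. Default `FALSE`: suitable means
#'   any non-unsuitable category (EI >= 1 under the published binning,
#'   with (0, 1) folded into marginal).
#' @param ei_layer EI matrix, only needed when `ei_gt_1 = TRUE`.
#' @return `data.frame` with one row per category (area in km^2 and % of
#'   regional land area) plus attributes `total_area` and `pct_suitable`.
#' @export
summarize_region <- function(category_layer, areas, mask,
                             ei_gt_1 = FALSE, ei_layer = NULL) {
  stopifnot(inherits(mask, "region_mask"))
  codes <- .category_codes(category_layer)
  sel <- mask$mask & !is.na(codes)
  if (!any(sel)) stop(sprintf("region '%s' contains no evaluated cells",
                              mask$name))
  total <- sum(areas[sel])
  cat_area <- vapply(1:4, function(k) sum(areas[sel & codes == k]),
                     numeric(1))
  pct <- 100 * cat_area / total
  if (ei_gt_1) {
    if (is.null(ei_layer)) stop("ei_gt_1 = TRUE requires ei_layer")
    suitable <- 100 * sum(areas[sel & ei_layer > 1]) / total
  } else {
    suitable <- sum(pct[2:4])
  }
  out <- data.frame(region = mask$name, category = .ei_categories,
                    area_km2 = cat_area, pct = pct)
  attr(out, "total_area") <- total
  attr(out, "pct_suitable") <- suitable
  out
}

#' Regional change table between two scenarios
#'
#' For each region: total land area (1e6 km^2), area-weighted percentage
#' per suitability category under both scenarios, percent suitable
#' (non-unsuitable), and two change metrics — `change_points` (percentage-
#' point difference of the suitable share, B - A) and `change_relative`
#' (`100 * (B - A) / A`). Both are reported because published change
#' columns mix the two conventions.
#'
#' @param current,future Category matrices from [run_grid] for the two
#'   scenarios, sharing one grid.
#' @param areas Cell-area matrix from [cell_areas].
#' @param masks List of [region_mask] objects.
#' @param ei_gt_1,ei_current,ei_future Strict suitable threshold option,
#'   see [summarize_region].
#' @return `data.frame` of class `change_table`, one row per region.
#' @export
change_table <- function(current, future, areas, masks,
                         ei_gt_1 = FALSE, ei_current = NULL,
                         ei_future = NULL) {
  stopifnot(identical(dim(.category_codes(current)),
                      dim(.category_codes(future))))
  if (inherits(masks, "region_mask")) masks <- list(masks)
  rows <- lapply(masks, function(mk) {
    a <- summarize_region(current, areas, mk, ei_gt_1, ei_current)
    b <- summarize_region(future, areas, mk, ei_gt_1, ei_future)
    sa <- attr(a, "pct_suitable"); sb <- attr(b, "pct_suitable")
    row <- data.frame(region = mk$name,
                      total_area_1e6km2 = attr(a, "total_area") / 1e6)
    for (k in 1:4) {
      row[[paste0("pct_", .ei_categories[k], "_A")]] <- a$pct[k]
      row[[paste0("pct_", .ei_categories[k], "_B")]] <- b$pct[k]
    }
    row$pct_suitable_A <- sa
    row$pct_suitable_B <- sb
    row$change_points <- sb - sa
    row$change_relative <- if (sa > 0) 100 * (sb - sa) / sa else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("change_table", class(out))
  out
}

#' Extract the four stress rasters from a model run
#'
#' @param result An `ei_grid` from [run_grid].
#' @param dir Optional directory; when given, each raster is written as
#'   CSV via [write_raster] (`cs.csv`, `hs.csv`, `ds.csv`, `ws.csv`).
#' @return Named list of matrices `cs`, `hs`, `ds`, `ws`.
#' @export
stress_maps <- function(result, dir = NULL) {
  stopifnot(inherits(result, "ei_grid"))
  out <- result[c("cs", "hs", "ds", "ws")]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      write_raster(out[[nm]], result$grid,
                   file.path(dir, paste0(nm, ".csv")))
  }
  out
}
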