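#' Clean an occurrence table
#'
#' Drops records with missing or physically invalid coordinates
#' (|lat| > 90, |lon| > 180) and exact duplicate (lon, lat) pairs, logging
#' the counts. Idempotent on an already-clean table.
#'
#' @param raw `data.frame` with columns `lon` and `lat` (extra columns are
#'   kept).
#' @return An `occurrence_set`: list with `records` (cleaned data.frame),
#'   `n_raw`, `n_clean`, `n_missing`, `n_invalid`, `n_duplicate`.
#' @export
clean_occurrences <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("lon", "lat") %in% names(raw)))
  n_raw <- nrow(raw)
  miss <- !is.finite(raw$lon) | !is.finite(raw$lat)
  kept <- raw[!miss, , drop = FALSE]
  invalid <- abs(kept$lat) > 90 | abs(kept$lon) > 180
  kept <- kept[!invalid, , drop = FALSE]
  dup <- duplicated(kept[, c("lon", "lat")])
  kept <- kept[!dup, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no occurrence records survive cleaning")
  rownames(kept) <- NULL
  structure(list(records = kept, n_raw = n_raw, n_clean = nrow(kept),
                 n_missing = sum(miss), n_invalid = sum(invalid),
                 n_duplicate = sum(dup)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d clean of %d raw (%d missing, %d invalid, %d duplicate)\n",
              x$n_clean, x$n_raw, x$n_missing, x$n_invalid, x$n_duplicate))
  invisible(x)
}

# Map lon/lat points to linear cell indices of a climate_grid (lats
# descending). Cell bounds are half-open: [west, east) x (south, north],
# so edge points are assigned deterministically and never double-counted.
# Off-grid points get NA.
.point_cells <- function(lon, lat, grid) {
  res <- grid$resolution
  west0 <- grid$lons[1] - res / 2
  north0 <- grid$lats[1] + res / 2
  ci <- floor((lon - west0) / res) + 1
  ri <- floor((north0 - lat) / res) + 1
  # points exactly on the northern grid edge belong to the top row
  ri[lat == north0] <- 1
  off <- ci < 1 | ci > length(grid$lons) | ri < 1 | ri > length(grid$lats)
  idx <- (ci - 1) * length(grid$lats) + ri
  idx[off] <- NA_integer_
  as.integer(idx)
}

#' Overlay occurrences on a suitability surface
#'
#' Maps each record to its containing cell (half-open bounds) and reports
#' counts per suitability category and the fraction of records in cells
#' with `EI >= suitable_min`. Off-grid and masked-cell records are excluded
#' and counted. The result is invariant to record order.
#'
#' @param occ An `occurrence_set` (or a plain data.frame with lon/lat).
#' @param result An `ei_grid` from [run_grid].
#' @param suitable_min EI threshold (default 1).
#' @return List with `n_used`, `n_off_grid`, `counts` (per category),
#'   `n_suitable` and `suitable_fraction`.
#' @export
overlay_fraction <- function(occ, result, suitable_min = 1) {
  pts <- if (inherits(occ, "occurrence_set")) occ$records else occ
  stopifnot(inherits(result, "ei_grid"))
  cells <- .point_cells(pts$lon, pts$lat, result$grid)
  ei <- result$ei[cells]
  off <- is.na(cells) | is.na(ei)
  ei <- ei[!off]
  cat <- classify_ei(ei)
  n_used <- length(ei)
  if (n_used == 0L) stop("no occurrence records fall on evaluated cells")
  n_suit <- sum(ei >= suitable_min)
  list(n_used = n_used, n_off_grid = sum(off),
       counts = table(cat, dnn = NULL),
       n_suitable = n_suit,
       suitable_fraction = n_suit / n_used)
}

#' Split occurrences into fit and validation sets by region
#'
#' Records whose containing cell lies inside the mask form the validation
#' set; all others (including off-grid records) form the fit set. The two
#' sets are disjoint and exhaustive.
#'
#' @param occ An `occurrence_set`.
#' @param mask A [region_mask].
#' @param grid The [climate_grid] the mask is aligned to.
#' @return List with `fit` and `validation` data.frames.
#' @export
holdout_split <- function(occ, mask, grid) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(mask, "region_mask"))
  pts <- occ$records
  cells <- .point_cells(pts$lon, pts$lat, grid)
  inside <- !is.na(cells) & mask$mask[cells]
  if (all(inside)) warning("fit set is empty")
  if (!any(inside)) warning("validation set is empty")
  list(fit = pts[!inside, , drop = FALSE],
       validation = pts[inside, , drop = FALSE])
}
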