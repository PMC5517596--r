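#' Gridded monthly climatology
#'
#' A `climate_grid` holds the five monthly climate variables a CLIMEX-style
#' model consumes on a regular lon/lat grid: average minimum and maximum
#' temperature (degrees C), total precipitation (mm/month) and relative
#' humidity at 09:00 and 15:00 (fractions in \[0, 1\]), each as an
#' `nlat x nlon x 12` array, plus a logical land mask. Latitudes are stored
#' north-to-south (descending); longitudes increasing. Coordinates are cell
#' centres.
#'
#' Cells that violate the physical invariants (`tmax >= tmin`, `precip >= 0`,
#' humidity in \[0, 1\], all values finite) are masked out with a warning
#' giving the count; values under the mask are set to `NA`.
#'
#' @param lons Numeric vector of cell-centre longitudes, strictly increasing,
#'   uniform step.
#' @param lats Numeric vector of cell-centre latitudes, strictly monotone,
#'   uniform step. Stored descending internally.
#' @param tmin,tmax,precip,rh09,rh15 Arrays `length(lats) x length(lons) x 12`.
#' @param land_mask Logical matrix `length(lats) x length(lons)`; defaults to
#'   all-land.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(lons, lats, tmin, tmax, precip, rh09, rh15,
                         land_mask = NULL) {
  lons <- as.numeric(lons); lats <- as.numeric(lats)
  if (length(lons) < 1L || length(lats) < 1L)
    stop("empty coordinate vector")
  if (length(lons) > 1L) {
    dl <- diff(lons)
    if (any(dl <= 0)) stop("lons must be strictly increasing")
    if (max(abs(dl - dl[1])) > 1e-8) stop("lons must have a uniform step")
  }
  if (length(lats) > 1L) {
    dphi <- diff(lats)
    if (!(all(dphi > 0) || all(dphi < 0))) stop("lats must be strictly monotone")
    if (max(abs(abs(dphi) - abs(dphi[1]))) > 1e-8)
      stop("lats must have a uniform step")
  }
  res <- if (length(lons) > 1L) abs(lons[2] - lons[1])
         else if (length(lats) > 1L) abs(lats[2] - lats[1]) else 1

  dims <- c(length(lats), length(lons), 12L)
  vars <- list(tmin = tmin, tmax = tmax, precip = precip,
               rh09 = rh09, rh15 = rh15)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (!identical(dim(v), as.integer(dims)) &&
        !identical(dim(v), dims))
      stop(sprintf("variable '%s' must be a %d x %d x 12 array",
                   nm, dims[1], dims[2]))
    storage.mode(vars[[nm]]) <- "double"
  }
  if (is.null(land_mask)) land_mask <- matrix(TRUE, dims[1], dims[2])
  if (!identical(dim(land_mask), dims[1:2]) || !is.logical(land_mask))
    stop("land_mask must be a logical nlat x nlon matrix")

  # normalize latitude order to descending north -> south
  if (length(lats) > 1L && lats[2] > lats[1]) {
    ord <- rev(seq_along(lats))
    lats <- lats[ord]
    land_mask <- land_mask[ord, , drop = FALSE]
    vars <- lapply(vars, function(v) v[ord, , , drop = FALSE])
  }

  # invariant screening: offending land cells get masked out
  bad <- matrix(FALSE, dims[1], dims[2])
  for (nm in names(vars)) {
    nf <- apply(!is.finite(vars[[nm]]), c(1, 2), any)
    bad <- bad | nf
  }
  bad <- bad | apply(vars$tmax < vars$tmin, c(1, 2), any)
  bad <- bad | apply(vars$precip < 0, c(1, 2), any)
  bad <- bad | apply(vars$rh09 < 0 | vars$rh09 > 1, c(1, 2), any)
  bad <- bad | apply(vars$rh15 < 0 | vars$rh15 > 1, c(1, 2), any)
  bad[is.na(bad)] <- TRUE
  n_bad <- sum(bad & land_mask)
  if (n_bad > 0) {
    warning(sprintf("%d cell(s) violate climate invariants; masked out", n_bad))
    land_mask <- land_mask & !bad
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    v[array(!land_mask, dim = dims)] <- NA_real_
    vars[[nm]] <- v
  }

  structure(
    list(lons = lons, lats = lats, resolution = res,
         tmin = vars$tmin, tmax = vars$tmax, precip = vars$precip,
         rh09 = vars$rh09, rh15 = vars$rh15, land_mask = land_mask),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells at %.3g deg (%d land)\n",
              length(x$lats), length(x$lons), x$resolution, sum(x$land_mask)))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]\n",
              min(x$lons), max(x$lons), min(x$lats), max(x$lats)))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) c(length(x$lats), length(x$lons))

.grid_var_names <- c("tmin", "tmax", "prec", "rh09", "rh15")

#' Read a gridded monthly climatology
#'
#' Supported on-disk format is the flat-text CLIMEX-style CSV dialect
#' (`climex_csv`): one row per cell with columns `lon`, `lat`, then the five
#' variables month-minor (`tmin01..tmin12, tmax01..tmax12, prec01..prec12,
#' rh0901..rh0912, rh1501..rh1512`), header required. Sea/masked cells may be
#' omitted or carry `NA` values. `netcdf` and `geotiff_stack` are part of the
#' interface but require raster/NetCDF system libraries that are not
#' bundled; requesting them raises an informative error.
#'
#' @param path File to read.
#' @param format One of `"climex_csv"`, `"netcdf"`, `"geotiff_stack"`.
#' @return A validated [climate_grid].
#' @export
read_climate_grid <- function(path, format = c("climex_csv", "netcdf",
                                               "geotiff_stack")) {
  format <- match.arg(format)
  if (format != "climex_csv")
    stop(sprintf(paste0("format '%s' requires an optional raster backend ",
                        "(ncdf4/terra) that is not installed; ",
                        "use 'climex_csv'"), format))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path)
  need <- c("lon", "lat",
            sprintf("%s%02d", rep(.grid_var_names, each = 12), 1:12))
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0)
    stop(sprintf("climex_csv missing column(s): %s",
                 paste(utils::head(miss, 5), collapse = ", ")))

  lons <- sort(unique(dt$lon))
  lats <- sort(unique(dt$lat), decreasing = TRUE)
  nlat <- length(lats); nlon <- length(lons)
  ri <- match(dt$lat, lats); ci <- match(dt$lon, lons)
  idx <- cbind(ri, ci)

  arr <- function(var) {
    a <- array(NA_real_, c(nlat, nlon, 12))
    for (m in 1:12) {
      layer <- matrix(NA_real_, nlat, nlon)
      layer[idx] <- dt[[sprintf("%s%02d", var, m)]]
      a[, , m] <- layer
    }
    a
  }
  tmin <- arr("tmin"); tmax <- arr("tmax"); prec <- arr("prec")
  rh09 <- arr("rh09"); rh15 <- arr("rh15")
  filled <- matrix(FALSE, nlat, nlon)
  filled[idx] <- TRUE
  present <- filled & !apply(is.na(tmin), c(1, 2), all)
  climate_grid(lons, lats, tmin, tmax, prec, rh09, rh15, land_mask = present)
}

#' Write a gridded monthly climatology
#'
#' Serializes a [climate_grid] to the `climex_csv` dialect (see
#' [read_climate_grid]). Masked cells are written with `NA` values so that
#' the grid shape round-trips exactly.
#'
#' @param grid A [climate_grid].
#' @param path Output file.
#' @param format Only `"climex_csv"` is supported on disk.
#' @export
write_climate_grid <- function(grid, path, format = "climex_csv") {
  if (format != "climex_csv")
    stop(sprintf("format '%s' not supported for writing; use 'climex_csv'",
                 format))
  stopifnot(inherits(grid, "climate_grid"))
  nlat <- length(grid$lats); nlon <- length(grid$lons)
  dt <- data.table::data.table(
    lon = rep(grid$lons, each = nlat),
    lat = rep(grid$lats, times = nlon))
  for (v in .grid_var_names) {
    src <- switch(v, prec = grid$precip, grid[[v]])
    for (m in 1:12) dt[[sprintf("%s%02d", v, m)]] <- as.vector(src[, , m])
  }
  data.table::fwrite(dt, path, na = "NA")
  invisible(path)
}

#' Write a single real-valued raster layer
#'
#' Writes one per-cell layer (e.g. an EI map) aligned to a grid as a flat
#' `lon,lat,value` CSV. `NA` cells are written with the nodata sentinel.
#' The companion [read_raster] restores values, sentinel and mask exactly.
#'
#' @param layer Numeric matrix `nlat x nlon` aligned to `grid`.
#' @param grid A [climate_grid] providing coordinates.
#' @param path Output file.
#' @param format Only `"csv"` is supported (see [read_climate_grid] for why
#'   the raster backends are absent).
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @export
write_raster <- function(layer, grid, path, format = "csv", nodata = -9999) {
  if (format != "csv")
    stop(sprintf("format '%s' requires an optional raster backend; use 'csv'",
                 format))
  if (!is.matrix(layer) ||
      !identical(dim(layer), c(length(grid$lats), length(grid$lons))))
    stop("layer shape does not match grid")
  nlat <- nrow(layer); nlon <- ncol(layer)
  val <- as.vector(layer)
  val[is.na(val)] <- nodata
  dt <- data.table::data.table(
    lon = rep(grid$lons, each = nlat),
    lat = rep(grid$lats, times = nlon),
    value = val)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a raster layer written by [write_raster]
#'
#' @param path File to read.
#' @param nodata Sentinel mapped back to `NA` (default -9999). Use
#'   `nodata = NULL` to keep sentinels as values.
#' @return List with `lons`, `lats` (descending) and `layer` matrix.
#' @export
read_raster <- function(path, nodata = -9999) {
  dt <- data.table::fread(path)
  stopifnot(all(c("lon", "lat", "value") %in% names(dt)))
  lons <- sort(unique(dt$lon))
  lats <- sort(unique(dt$lat), decreasing = TRUE)
  layer <- matrix(NA_real_, length(lats), length(lons))
  layer[cbind(match(dt$lat, lats), match(dt$lon, lons))] <- dt$value
  if (!is.null(nodata)) layer[layer == nodata] <- NA_real_
  list(lons = lons, lats = lats, layer = layer)
}
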