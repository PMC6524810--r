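#' @import data.table
#' @importFrom stats cor sd rpois runif rnorm rbinom quantile
#' @importFrom utils head tail
NULL

#' Gear classes recognized in vessel tables
#'
#' The six gear classes of the AIS fishing-detection output: trawlers,
#' fixed gear, drifting longlines, purse seines, squid jiggers and a
#' residual "other" class. After the purse-seine split ([split_purse_seiners()])
#' effort is stratified by *fleet*, where `purse_seines` is replaced by
#' `purse_coastal` and `purse_high_seas`.
#'
#' @export
GEAR_CLASSES <- c("trawlers", "fixed_gear", "drifting_longlines",
                  "purse_seines", "squid_jigger", "other")

#' @rdname GEAR_CLASSES
#' @export
FLEET_CLASSES <- c("trawlers", "fixed_gear", "drifting_longlines",
                   "purse_coastal", "purse_high_seas", "squid_jigger", "other")

# kilometers per nautical mile (SI definition)
KM_PER_NM <- 1.852
# conventional mean Earth radius, km
EARTH_RADIUS_KM <- 6371.0

#' Define a global longitude/latitude grid
#'
#' Cells are addressed by their lower-left corner on half-open intervals
#' `[lon, lon + res) x [lat, lat + res)` with origin (-180, -90), so every
#' point on Earth maps to exactly one cell (longitude 180 wraps to -180,
#' latitude 90 falls in the top row). Supported resolutions are 0.5, 1.0
#' and 4.0 degrees.
#'
#' @param resolution_deg cell size in degrees; one of 0.5, 1.0, 4.0.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(resolution_deg = 1.0) {
  if (!is.numeric(resolution_deg) || length(resolution_deg) != 1L ||
      !resolution_deg %in% c(0.5, 1.0, 4.0)) {
    stop("resolution_deg must be one of 0.5, 1.0, 4.0 (got ",
         paste(resolution_deg, collapse = ","), ")", call. = FALSE)
  }
  structure(list(
    res  = resolution_deg,
    nlon = as.integer(round(360 / resolution_deg)),
    nlat = as.integer(round(180 / resolution_deg))
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %.1f deg: %d x %d cells>\n", x$res, x$nlon, x$nlat))
  invisible(x)
}

same_grid <- function(a, b) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") && a$res == b$res
}

#' Map longitude/latitude to grid cell ids
#'
#' @param grid a [grid_spec()].
#' @param lon,lat numeric vectors in degrees; `lon` outside `[-180, 180)` is
#'   wrapped (in particular lon = 180 maps to -180); `lat = 90` is assigned
#'   to the top row.
#' @return integer cell ids in `1 .. nlon * nlat` (row-major from the
#'   south-west corner).
#' @export
lonlat_to_cell <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  lon <- ((lon + 180) %% 360) - 180
  i <- pmin(grid$nlon, floor((lon + 180) / grid$res) + 1)
  j <- pmin(grid$nlat, floor((lat + 90) / grid$res) + 1)
  as.integer((j - 1) * grid$nlon + i)
}

#' Cell centers for cell ids
#'
#' @param grid a [grid_spec()].
#' @param cell integer cell ids.
#' @return a `data.table` with columns `cell`, `lon`, `lat` (centers).
#' @export
cell_center <- function(grid, cell) {
  stopifnot(inherits(grid, "grid_spec"))
  cell <- as.integer(cell)
  i <- ((cell - 1L) %% grid$nlon) + 1L
  j <- ((cell - 1L) %/% grid$nlon) + 1L
  data.table(cell = cell,
             lon = -180 + (i - 0.5) * grid$res,
             lat = -90 + (j - 0.5) * grid$res)
}

#' Spherical cell areas in square kilometers
#'
#' @inheritParams cell_center
#' @return numeric vector of areas, km^2.
#' @export
cell_area_km2 <- function(grid, cell) {
  ctr <- cell_center(grid, cell)
  lat0 <- (ctr$lat - grid$res / 2) * pi / 180
  lat1 <- (ctr$lat + grid$res / 2) * pi / 180
  dlon <- grid$res * pi / 180
  EARTH_RADIUS_KM^2 * dlon * (sin(lat1) - sin(lat0))
}

#' Days in a calendar month
#'
#' @param year,month integer vectors (recycled).
#' @return integer day counts; leap Februaries have 29 days.
#' @export
days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

# table of all (year, month, days) in a span of whole years
month_table <- function(years) {
  mt <- CJ(year = as.integer(years), month = 1:12)
  mt[, days := days_in_month(year, month)]
  setkey(mt, year, month)
  mt[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("effortseas_input_error", "error")))
}
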