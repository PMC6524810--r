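# Distance-to-port handling: bilinear interpolation of a fine raster at
# grid-cell centers and effort-weighted variability profiles per distance
# bin with the low-effort discard rule.

#' Construct a distance raster
#'
#' A regular lon/lat raster of distances (km) at arbitrary (fine)
#' resolution; `NA` marks invalid (e.g. land) nodes.
#'
#' @param lon,lat strictly increasing node coordinate vectors (degrees).
#' @param values numeric matrix, `length(lon)` rows x `length(lat)`
#'   columns; distances in km, `NA` where invalid.
#' @return an object of class `distance_raster`.
#' @export
distance_raster <- function(lon, lat, values) {
  values <- as.matrix(values)
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0),
            nrow(values) == length(lon), ncol(values) == length(lat))
  if (any(values < 0, na.rm = TRUE)) input_error("negative distances in raster")
  structure(list(lon = lon, lat = lat, values = values),
            class = "distance_raster")
}

#' @export
print.distance_raster <- function(x, ...) {
  cat(sprintf("<distance_raster %d x %d nodes, lon [%.2f, %.2f], lat [%.2f, %.2f]>\n",
              length(x$lon), length(x$lat), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat)))
  invisible(x)
}

#' Read / write a distance raster as long-format CSV
#'
#' Columns `lon,lat,distance_km`; the node layout is recovered on read
#' (missing nodes become `NA`).
#'
#' @param path CSV path.
#' @export
read_distance_raster <- function(path) {
  d <- fread(path)
  if (!all(c("lon", "lat", "distance_km") %in% names(d))) {
    input_error("distance raster CSV must have columns lon,lat,distance_km")
  }
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  values <- matrix(NA_real_, length(lon), length(lat))
  values[cbind(match(d$lon, lon), match(d$lat, lat))] <- d$distance_km
  distance_raster(lon, lat, values)
}

#' @rdname read_distance_raster
#' @param raster a [distance_raster()].
#' @export
write_distance_raster <- function(raster, path) {
  d <- CJ(lat = raster$lat, lon = raster$lon)[, .(lon, lat)]
  d[, distance_km := raster$values[cbind(match(lon, raster$lon),
                                         match(lat, raster$lat))]]
  fwrite(d[!is.na(distance_km)], path)
  invisible(path)
}

# bilinear interpolation at query points; NA corners are dropped and the
# weights renormalized; all-NA neighborhoods and points outside the raster
# extent give NA
interp_raster <- function(raster, lon, lat) {
  nx <- length(raster$lon); ny <- length(raster$lat)
  i <- findInterval(lon, raster$lon)
  j <- findInterval(lat, raster$lat)
  out <- rep(NA_real_, length(lon))
  inside <- lon >= raster$lon[1] & lon <= raster$lon[nx] &
            lat >= raster$lat[1] & lat <= raster$lat[ny]
  i0 <- pmin(pmax(i, 1L), nx - 1L); j0 <- pmin(pmax(j, 1L), ny - 1L)
  tx <- (lon - raster$lon[i0]) / (raster$lon[i0 + 1L] - raster$lon[i0])
  ty <- (lat - raster$lat[j0]) / (raster$lat[j0 + 1L] - raster$lat[j0])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  v00 <- raster$values[cbind(i0, j0)]
  v10 <- raster$values[cbind(i0 + 1L, j0)]
  v01 <- raster$values[cbind(i0, j0 + 1L)]
  v11 <- raster$values[cbind(i0 + 1L, j0 + 1L)]
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  num <- ifelse(is.na(v00), 0, w00 * v00) + ifelse(is.na(v10), 0, w10 * v10) +
         ifelse(is.na(v01), 0, w01 * v01) + ifelse(is.na(v11), 0, w11 * v11)
  den <- ifelse(is.na(v00), 0, w00) + ifelse(is.na(v10), 0, w10) +
         ifelse(is.na(v01), 0, w01) + ifelse(is.na(v11), 0, w11)
  ok <- inside & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Interpolate a distance raster at grid-cell centers
#'
#' Bilinear interpolation of the (typically much finer) raster at each
#' requested cell's center. Cells outside the raster extent, or whose four
#' surrounding nodes are all invalid, are flagged with `NA` and excluded
#' from downstream profiles.
#'
#' @param raster a [distance_raster()].
#' @param grid a [grid_spec()].
#' @param cells integer cell ids (default: all cells whose centers fall in
#'   the raster extent).
#' @return a `data.table` with `cell`, `distance_km` (`NA` where flagged).
#' @export
distance_at_cells <- function(raster, grid, cells = NULL) {
  stopifnot(inherits(raster, "distance_raster"), inherits(grid, "grid_spec"))
  if (is.null(cells)) {
    lon_seq <- seq(-180 + grid$res / 2, 180 - grid$res / 2, by = grid$res)
    lat_seq <- seq(-90 + grid$res / 2, 90 - grid$res / 2, by = grid$res)
    lon_seq <- lon_seq[lon_seq >= min(raster$lon) & lon_seq <= max(raster$lon)]
    lat_seq <- lat_seq[lat_seq >= min(raster$lat) & lat_seq <= max(raster$lat)]
    pts <- CJ(lon = lon_seq, lat = lat_seq)
    cells <- lonlat_to_cell(grid, pts$lon, pts$lat)
  }
  ctr <- cell_center(grid, cells)
  data.table(cell = ctr$cell,
             distance_km = interp_raster(raster, ctr$lon, ctr$lat))
}

#' Effort-weighted variability per distance-to-port bin
#'
#' For each gear and contiguous half-open distance bin (default width 75
#' km), computes the mean local relative standard deviation over the
#' bin's cells weighted by their annual climatological effort. Bins whose
#' summed annual effort is below `discard_frac` (default 0.1%) of the
#' gear's global annual effort are flagged `retained = FALSE` (values are
#' still reported); so are empty bins.
#'
#' @param sd_map a [local_relative_sd()] result computed per gear.
#' @param clim the matching [climatology()] (weights and the discard rule).
#' @param distances a `data.table(cell, distance_km)` from
#'   [distance_at_cells()].
#' @param gears gears to profile (default: all in `clim`).
#' @param bin_width_km bin width, km (default 75).
#' @param discard_frac discard threshold as a fraction of the gear's
#'   global annual effort (default 0.001).
#' @return a `data.table` with `gear, bin_lo_km, bin_hi_km, weighted_sd,
#'   effort_share, n_cells, retained`.
#' @export
binned_variability <- function(sd_map, clim, distances, gears = NULL,
                               bin_width_km = 75, discard_frac = 0.001) {
  stopifnot(inherits(sd_map, "local_sd_map"), inherits(clim, "climatology_cube"))
  if (!isTRUE(sd_map$by_gear)) {
    input_error("binned_variability needs a per-gear local sd map")
  }
  if (!same_grid(sd_map$grid, clim$grid)) input_error("grid mismatch")
  gears <- gears %||% clim$gears
  ann <- climatology_annual(clim, by_gear = TRUE)
  d <- merge(sd_map$data, ann, by = c("gear", "cell"))
  d <- merge(d, distances, by = "cell")
  d <- d[gear %in% gears & !is.na(distance_km) & annual > 0]
  totals <- ann[gear %in% gears, .(total = sum(annual)), by = gear]
  d[, bin := floor(distance_km / bin_width_km)]
  prof <- d[, .(weighted_sd = sum(rel_sd * annual) / sum(annual),
                bin_effort = sum(annual), n_cells = .N),
            by = .(gear, bin)]
  # complete the bin range per gear so empty bins appear (discarded)
  full <- prof[, .(bin = 0:max(bin)), by = gear]
  prof <- prof[full, on = c("gear", "bin")]
  prof[is.na(bin_effort), `:=`(bin_effort = 0, n_cells = 0L)]
  prof <- prof[totals, on = "gear", nomatch = NULL]
  prof[, effort_share := bin_effort / total]
  prof[, retained := n_cells > 0L & effort_share >= discard_frac]
  prof[, `:=`(bin_lo_km = bin * bin_width_km,
              bin_hi_km = (bin + 1) * bin_width_km)]
  setorder(prof, gear, bin_lo_km)
  prof[, .(gear, bin_lo_km, bin_hi_km, weighted_sd, effort_share,
           n_cells, retained)]
}
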