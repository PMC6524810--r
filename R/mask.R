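# Cell masks (e.g. an EEZ): explicit sets of grid cells, optionally built
# from a polygon by the center-in-polygon rule.

#' Construct a cell mask
#'
#' @param grid a [grid_spec()].
#' @param cells integer cell ids belonging to the mask.
#' @param label descriptive label (e.g. `"Chinese EEZ"`).
#' @return an object of class `cell_mask`.
#' @export
cell_mask <- function(grid, cells, label = "mask") {
  stopifnot(inherits(grid, "grid_spec"))
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) && (min(cells) < 1L || max(cells) > grid$nlon * grid$nlat)) {
    input_error("mask contains cell ids outside the grid")
  }
  structure(list(grid = grid, cells = cells, label = label), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask '%s': %d cells at %.1f deg>\n",
              x$label, length(x$cells), x$grid$res))
  invisible(x)
}

#' Build a cell mask from a polygon
#'
#' A cell is a member iff its center lies inside the polygon (deterministic
#' and resolution-consistent; no fractional-overlap weighting).
#'
#' @param polygon a 2-column matrix of (lon, lat) vertices; rings need not
#'   be closed.
#' @param grid a [grid_spec()].
#' @param label mask label.
#' @return a [cell_mask()].
#' @export
mask_from_polygon <- function(polygon, grid, label = "mask") {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    input_error("degenerate polygon: need >= 3 (lon, lat) vertices")
  }
  # restrict the candidate cells to the polygon bounding box
  rng_lon <- range(polygon[, 1]); rng_lat <- range(polygon[, 2])
  lon_seq <- seq(-180 + grid$res / 2, 180 - grid$res / 2, by = grid$res)
  lat_seq <- seq(-90 + grid$res / 2, 90 - grid$res / 2, by = grid$res)
  lon_seq <- lon_seq[lon_seq >= rng_lon[1] - grid$res & lon_seq <= rng_lon[2] + grid$res]
  lat_seq <- lat_seq[lat_seq >= rng_lat[1] - grid$res & lat_seq <= rng_lat[2] + grid$res]
  if (!length(lon_seq) || !length(lat_seq)) {
    warning("polygon does not intersect the grid; empty mask", call. = FALSE)
    return(cell_mask(grid, integer(0), label))
  }
  pts <- as.matrix(CJ(lon = lon_seq, lat = lat_seq))
  # mgcv::in.out expects closed boundary loops
  bnd <- rbind(polygon, polygon[1, ])
  inside <- mgcv::in.out(bnd, pts)
  if (!any(inside)) {
    warning("polygon contains no cell centers; empty mask", call. = FALSE)
    return(cell_mask(grid, integer(0), label))
  }
  cell_mask(grid, lonlat_to_cell(grid, pts[inside, 1], pts[inside, 2]), label)
}

#' Read a mask from GeoJSON or a CSV of cell centers
#'
#' GeoJSON `Polygon`/`MultiPolygon` geometries (or a `Feature`/
#' `FeatureCollection` wrapping one) are converted by the center-in-polygon
#' rule; a CSV must have columns `lon,lat` listing member cell centers.
#'
#' @param path file path (`.geojson`/`.json` or `.csv`).
#' @param grid a [grid_spec()].
#' @param label mask label.
#' @return a [cell_mask()].
#' @export
read_mask <- function(path, grid, label = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    polys <- geojson_polygons(gj)
    if (!length(polys)) input_error("no polygon geometry found in ", path)
    cells <- integer(0)
    for (p in polys) {
      cells <- union(cells, mask_from_polygon(p, grid, label %||% "mask")$cells)
    }
    cell_mask(grid, cells, label %||% basename(path))
  } else {
    d <- fread(path)
    if (!all(c("lon", "lat") %in% names(d))) {
      input_error("mask CSV must have columns lon,lat")
    }
    cell_mask(grid, lonlat_to_cell(grid, d$lon, d$lat), label %||% basename(path))
  }
}

# extract outer rings (lon,lat matrices) from parsed GeoJSON
geojson_polygons <- function(gj) {
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  from_geometry <- function(geom) {
    switch(geom$type %||% "",
      Polygon = list(ring_to_matrix(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) ring_to_matrix(p[[1]])),
      list())
  }
  switch(gj$type %||% "",
    Polygon = ,
    MultiPolygon = from_geometry(gj),
    Feature = from_geometry(gj$geometry),
    FeatureCollection = do.call(c, lapply(gj$features, function(f) from_geometry(f$geometry))),
    list())
}

#' Write a polygon as a GeoJSON Feature
#'
#' @param polygon 2-column (lon, lat) vertex matrix (closed automatically).
#' @param path output path.
#' @param properties named list stored as the feature's properties.
#' @export
write_geojson_polygon <- function(polygon, path, properties = list()) {
  polygon <- as.matrix(polygon)
  if (!all(polygon[1, ] == polygon[nrow(polygon), ])) {
    polygon <- rbind(polygon, polygon[1, ])
  }
  ring <- lapply(seq_len(nrow(polygon)), function(i) c(polygon[i, 1], polygon[i, 2]))
  feature <- list(
    type = "Feature",
    properties = properties,
    geometry = list(type = "Polygon", coordinates = list(ring))
  )
  jsonlite::write_json(feature, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
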