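# Ingest of daily per-vessel fishing records and vessel metadata, the
# continuity filter, the purse-seine split, and rasterization to
# vessel-day effort grids.

#' Read a vessel metadata table
#'
#' Expects a CSV with header `vessel_id,gear_class,length_m` and an optional
#' `mean_shore_distance_nm` column. Gear strings outside the six recognized
#' classes are mapped to `"other"` with a warning.
#'
#' @param path path to the CSV file.
#' @return a `data.table` with columns `vessel_id` (character), `gear_class`
#'   (one of [GEAR_CLASSES]), `length_m` (numeric, `NA` when missing) and
#'   `mean_shore_distance_nm` (numeric, `NA` when absent).
#' @export
read_vessel_table <- function(path) {
  vt <- fread(path)
  if (nrow(vt) == 0L) input_error("vessel table is empty: ", path)
  for (col in c("vessel_id", "gear_class")) {
    if (!col %in% names(vt)) {
      input_error("vessel table is missing mandatory column '", col, "'")
    }
  }
  if (!"length_m" %in% names(vt)) vt[, length_m := NA_real_]
  vt[, vessel_id := as.character(vessel_id)]
  vt[, gear_class := as.character(gear_class)]
  vt[, length_m := as.numeric(length_m)]
  if (!"mean_shore_distance_nm" %in% names(vt)) {
    vt[, mean_shore_distance_nm := NA_real_]
  } else {
    vt[, mean_shore_distance_nm := as.numeric(mean_shore_distance_nm)]
  }
  bad <- !vt$gear_class %in% GEAR_CLASSES
  if (any(bad)) {
    warning(sum(bad), " vessel(s) with unrecognized gear class (",
            paste(unique(vt$gear_class[bad]), collapse = ", "),
            ") mapped to 'other'", call. = FALSE)
    vt[bad, gear_class := "other"]
  }
  if (anyNA(vt$length_m) || any(stats::na.omit(vt$length_m) < 0)) {
    if (any(stats::na.omit(vt$length_m) < 0)) {
      input_error("negative vessel length in vessel table")
    }
  }
  vt[, .(vessel_id, gear_class, length_m, mean_shore_distance_nm)]
}

#' Read daily per-vessel fishing records
#'
#' Expects a CSV with header `vessel_id,date,lat,lon,is_fishing` (dates
#' ISO-8601, `is_fishing` in 0/1). Rows flagged not fishing are dropped;
#' rows with unparseable dates or out-of-range coordinates are rejected and
#' counted (a hard error is raised when more than half of all rows are
#' rejected). Longitude 180 wraps to -180.
#'
#' @param path path to the CSV file.
#' @param vessel_table optional vessel table; when given, records whose
#'   vessel id is absent from it are rejected too.
#' @return a `data.table` with columns `vessel_id`, `date` (`IDate`), `lat`,
#'   `lon`; the number of rejected rows is attached as attribute
#'   `"n_rejected"`.
#' @export
read_fishing_records <- function(path, vessel_table = NULL) {
  rec <- fread(path)
  for (col in c("vessel_id", "date", "lat", "lon", "is_fishing")) {
    if (!col %in% names(rec)) {
      input_error("fishing-record file is missing column '", col, "'")
    }
  }
  n0 <- nrow(rec)
  rec[, date := as.IDate(as.character(date), format = "%Y-%m-%d")]
  ok <- !is.na(rec$date) &
    is.finite(rec$lat) & rec$lat >= -90 & rec$lat <= 90 &
    is.finite(rec$lon) & rec$lon >= -180 & rec$lon <= 180
  if (!is.null(vessel_table)) {
    ok <- ok & rec$vessel_id %in% vessel_table$vessel_id
  }
  n_rejected <- sum(!ok)
  if (n0 > 0L && n_rejected > 0.5 * n0) {
    input_error("more than 50% of fishing records rejected (",
                n_rejected, " of ", n0, ")")
  }
  rec <- rec[ok & is_fishing == 1L]
  rec[lon == 180, lon := -180]
  out <- rec[, .(vessel_id = as.character(vessel_id), date, lat, lon)]
  setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Keep only vessels continually active through the analysis window
#'
#' A vessel is retained iff it has at least one fishing record in every
#' calendar year of `years` (the weakest reading of "continually active";
#' stricter windows can be passed). Records of all other vessels are
#' removed. The kept/dropped vessel counts are attached as attribute
#' `"continuity"`.
#'
#' @param records a record table from [read_fishing_records()].
#' @param years integer vector of calendar years (default 2015:2017).
#' @return the filtered record table.
#' @export
filter_continuous_vessels <- function(records, years = 2015:2017) {
  yr <- data.table::year(records$date)
  act <- unique(data.table(vessel_id = records$vessel_id, year = yr))
  keep <- act[year %in% years, .(n = .N), by = vessel_id][n == length(years), vessel_id]
  out <- records[vessel_id %in% keep]
  n_all <- length(unique(records$vessel_id))
  if (length(keep) == 0L) {
    warning("no vessels active in every year of ",
            paste(range(years), collapse = "-"), call. = FALSE)
  }
  setattr(out, "continuity", list(kept = length(keep), dropped = n_all - length(keep)))
  out[]
}

#' Split purse seiners into coastal and high-seas fleets
#'
#' A purse seiner is classified high-seas iff its length exceeds 40 m and
#' its mean fishing distance from shore exceeds 50 nm; otherwise coastal.
#' The result is a `fleet` column: gear classes other than `purse_seines`
#' are carried over unchanged. When `mean_shore_distance_nm` is missing it
#' is computed from the vessel's fishing positions against a shore-distance
#' raster (if both are supplied); a purse vessel with a missing length is
#' classified coastal with a warning.
#'
#' @param vessel_table a table from [read_vessel_table()].
#' @param records optional record table, used with `shore_raster` to derive
#'   missing mean shore distances.
#' @param shore_raster optional [distance_raster()] of distance to shore, km.
#' @return the vessel table with an added `fleet` column (values in
#'   [FLEET_CLASSES]).
#' @export
split_purse_seiners <- function(vessel_table, records = NULL, shore_raster = NULL) {
  vt <- copy(vessel_table)
  need <- vt$gear_class == "purse_seines" & is.na(vt$mean_shore_distance_nm)
  if (any(need) && !is.null(records) && !is.null(shore_raster)) {
    pos <- records[vessel_id %in% vt$vessel_id[need]]
    if (nrow(pos)) {
      pos[, dist_km := interp_raster(shore_raster, lon, lat)]
      md <- pos[, .(mean_shore_distance_nm = mean(dist_km, na.rm = TRUE) / KM_PER_NM),
                by = vessel_id]
      vt[md, on = "vessel_id",
         mean_shore_distance_nm := fifelse(is.na(mean_shore_distance_nm),
                                           i.mean_shore_distance_nm,
                                           mean_shore_distance_nm)]
    }
  }
  vt[, fleet := gear_class]
  purse <- vt$gear_class == "purse_seines"
  nolen <- purse & is.na(vt$length_m)
  if (any(nolen)) {
    warning(sum(nolen), " purse seiner(s) with missing length classified coastal",
            call. = FALSE)
  }
  hs <- purse & !is.na(vt$length_m) & vt$length_m > 40 &
    !is.na(vt$mean_shore_distance_nm) & vt$mean_shore_distance_nm > 50
  vt[purse, fleet := "purse_coastal"]
  vt[hs, fleet := "purse_high_seas"]
  vt[]
}

#' Rasterize records to daily vessel-day counts
#'
#' One vessel fishing at least once in a cell on a date contributes exactly
#' one vessel-day to that cell, regardless of the number of position
#' reports; a vessel visiting k distinct cells on one date contributes one
#' vessel-day in each.
#'
#' @param records a record table (`vessel_id`, `date`, `lat`, `lon`).
#' @param vessel_table a vessel table; its `fleet` column (or `gear_class`
#'   when no split has been applied) labels the counts.
#' @param grid a [grid_spec()].
#' @return a `data.table` with columns `gear`, `date`, `cell`, `n`.
#' @export
rasterize_daily <- function(records, vessel_table, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  gear_col <- if ("fleet" %in% names(vessel_table)) "fleet" else "gear_class"
  rec <- records[, .(vessel_id, date, cell = lonlat_to_cell(grid, lon, lat))]
  rec <- unique(rec, by = c("vessel_id", "date", "cell"))
  lab <- vessel_table[, .(vessel_id, gear = get(gear_col))]
  rec <- lab[rec, on = "vessel_id"]
  if (anyNA(rec$gear)) {
    input_error("records reference vessels absent from the vessel table")
  }
  out <- rec[, .(n = .N), by = .(gear, date, cell)]
  setkey(out, gear, date, cell)
  out[]
}
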