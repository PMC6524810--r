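# Monthly effort grids: the central container of the pipeline. Values are
# e_g(i,j) in fishing-vessel-days per day (monthly vessel-day sum divided
# by the number of days in the month), stored sparsely (zero cells
# implicit).

#' Construct a monthly effort grid
#'
#' @param data a `data.table` with columns `gear`, `year`, `month`, `cell`,
#'   `effort` (vessel-days per day; nonnegative).
#' @param grid a [grid_spec()].
#' @param months optional `data.table(year, month, days)` giving the months
#'   covered (derived from `data` when omitted).
#' @param gears optional character vector of gear/fleet labels covered.
#' @return an object of class `monthly_effort_grid`.
#' @export
monthly_effort_grid <- function(data, grid, months = NULL, gears = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  data <- as.data.table(data)
  stopifnot(all(c("gear", "year", "month", "cell", "effort") %in% names(data)))
  if (nrow(data) && min(data$effort) < 0) {
    input_error("negative effort in monthly grid")
  }
  if (is.null(months)) {
    months <- unique(data[, .(year, month)])
    months[, days := days_in_month(year, month)]
    setkey(months, year, month)
  }
  structure(list(
    data   = data[effort > 0],
    grid   = grid,
    months = months,
    gears  = gears %||% sort(unique(data$gear))
  ), class = "monthly_effort_grid")
}

#' @export
print.monthly_effort_grid <- function(x, ...) {
  cat(sprintf("<monthly_effort_grid %.1f deg, %d months, %d gears, %d nonzero cell-months>\n",
              x$grid$res, nrow(x$months), length(x$gears), nrow(x$data)))
  invisible(x)
}

#' Total retained vessel-days in a monthly grid
#'
#' Multiplying each value by the days in its month and summing recovers the
#' vessel-day count exactly (conservation).
#'
#' @param meg a [monthly_effort_grid()].
#' @return a single number of vessel-days.
#' @export
total_vessel_days <- function(meg) {
  d <- meg$data[meg$months, on = c("year", "month"), nomatch = NULL]
  sum(d$effort * d$days)
}

#' Aggregate daily vessel-day counts to a monthly effort grid
#'
#' Monthly local effort is the vessel-day sum over the month divided by the
#' number of days in that month (leap Februaries use 29). Partial leading
#' or trailing months (detected from `coverage`) are excluded with a
#' warning.
#'
#' @param daily daily counts from [rasterize_daily()].
#' @param grid the [grid_spec()] the counts were rasterized on.
#' @param coverage length-2 Date vector of the first and last day covered
#'   by the input stream (defaults to the range of dates present).
#' @return a [monthly_effort_grid()].
#' @export
monthly_aggregate <- function(daily, grid, coverage = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(daily) == 0L) input_error("no daily counts to aggregate")
  coverage <- as.IDate(coverage %||% range(daily$date))
  first_full <- if (data.table::mday(coverage[1]) == 1L) {
    c(data.table::year(coverage[1]), data.table::month(coverage[1]))
  } else {
    y <- data.table::year(coverage[1]); m <- data.table::month(coverage[1]) + 1L
    if (m == 13L) c(y + 1L, 1L) else c(y, m)
  }
  last_cov <- c(data.table::year(coverage[2]), data.table::month(coverage[2]))
  last_full <- if (data.table::mday(coverage[2]) ==
                   days_in_month(last_cov[1], last_cov[2])) {
    last_cov
  } else {
    y <- last_cov[1]; m <- last_cov[2] - 1L
    if (m == 0L) c(y - 1L, 12L) else c(y, m)
  }
  lo <- first_full[1] * 12L + first_full[2]
  hi <- last_full[1] * 12L + last_full[2]
  if (hi < lo) input_error("coverage contains no complete calendar month")
  dd <- copy(daily)
  dd[, `:=`(year = data.table::year(date), month = data.table::month(date))]
  idx <- dd$year * 12L + dd$month
  if (any(idx < lo | idx > hi)) {
    warning("daily counts in partial months excluded from aggregation",
            call. = FALSE)
    dd <- dd[idx >= lo & idx <= hi]
  }
  ym <- CJ(k = lo:hi)[, .(year = (k - 1L) %/% 12L, month = ((k - 1L) %% 12L) + 1L)]
  months <- ym[, .(year, month, days = days_in_month(year, month))]
  setkey(months, year, month)
  agg <- dd[, .(vessel_days = sum(n)), by = .(gear, year, month, cell)]
  agg <- agg[months, on = c("year", "month"), nomatch = NULL]
  agg[, effort := vessel_days / days]
  monthly_effort_grid(agg[, .(gear, year, month, cell, effort)], grid,
                      months = months)
}

#' Zero a monthly grid inside or outside a cell mask
#'
#' `mode = "remove"` zeroes cells in the mask, `mode = "keep"` zeroes cells
#' outside it; the two partitions always sum back to the input. The
#' vessel-day totals of both partitions are stored in the result's
#' `mask_info` element.
#'
#' @param meg a [monthly_effort_grid()].
#' @param mask a [cell_mask()] on the same grid.
#' @param mode `"remove"` or `"keep"`.
#' @return a [monthly_effort_grid()] with `mask_info`.
#' @export
apply_mask <- function(meg, mask, mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  stopifnot(inherits(meg, "monthly_effort_grid"), inherits(mask, "cell_mask"))
  if (!same_grid(meg$grid, mask$grid)) {
    input_error("mask grid (", mask$grid$res, " deg) does not match effort grid (",
                meg$grid$res, " deg)")
  }
  inmask <- meg$data$cell %in% mask$cells
  keep <- if (mode == "remove") !inmask else inmask
  vd <- function(d) {
    if (nrow(d) == 0L) return(0)
    dd <- d[meg$months, on = c("year", "month"), nomatch = NULL]
    sum(dd$effort * dd$days)
  }
  out <- monthly_effort_grid(meg$data[keep], meg$grid, months = meg$months,
                             gears = meg$gears)
  out$mask_info <- list(label = mask$label, mode = mode,
                        masked_vessel_days = vd(meg$data[inmask]),
                        unmasked_vessel_days = vd(meg$data[!inmask]))
  out
}

#' Write / read a monthly effort grid as long-format CSV
#'
#' Columns `gear,year,month,lon,lat,effort_per_day` with cell centers; the
#' grid resolution and month span are recovered on read.
#'
#' @param meg a [monthly_effort_grid()].
#' @param path CSV path.
#' @export
write_monthly_csv <- function(meg, path) {
  ctr <- cell_center(meg$grid, meg$data$cell)
  out <- data.table(gear = meg$data$gear, year = meg$data$year,
                    month = meg$data$month, lon = ctr$lon, lat = ctr$lat,
                    effort_per_day = meg$data$effort)
  setorder(out, gear, year, month, lon, lat)
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_monthly_csv
#' @param resolution_deg grid resolution of the file being read.
#' @param months optional month table when the file does not span all
#'   months of the analysis window.
#' @export
read_monthly_csv <- function(path, resolution_deg, months = NULL) {
  grid <- grid_spec(resolution_deg)
  d <- fread(path)
  stopifnot(all(c("gear", "year", "month", "lon", "lat", "effort_per_day") %in% names(d)))
  d[, cell := lonlat_to_cell(grid, lon, lat)]
  if (is.null(months)) months <- month_table(sort(unique(d$year)))
  monthly_effort_grid(d[, .(gear, year, month, cell, effort = effort_per_day)],
                      grid, months = months)
}
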