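# Synthetic AIS-like data with fully known seasonal structure: parametric
# gear-specific spatial fields with cosine seasonal forcing, a summer
# moratorium confined to an EEZ band, boreal-winter holiday deficits of a
# stated whole-day magnitude, Poisson vessel-day sampling, and vessel
# metadata consistent with the continuity filter and the purse-seine
# split. Every injected parameter is recorded so the pipeline can be
# validated end to end.

#' Parameterize a synthetic effort scenario
#'
#' The defaults describe a 30 deg x 24 deg ocean basin on a 1 degree grid
#' with a meridional coastline on its western edge, three ports on the
#' coast, an EEZ band along the coast hosting a summer moratorium (the
#' observed closure windows), winter holiday deficits of 4/4/2.5 days,
#' gear shares 53/15/13/11/4/4 with purse seiners split 55% coastal, and
#' cosine seasonal cycles whose peak month varies by latitude band.
#' Coastal fleets (trawlers, fixed gear, coastal purse seiners)
#' concentrate within `coastal_max_km` of the coast with an exponential
#' fall-off; the remaining fleets cover the basin uniformly. With
#' `conserve_global = TRUE` (default) the seasonal forcing redistributes
#' each fleet's effort spatially while keeping its global monthly total
#' constant, so only holidays and the moratorium move the global series.
#'
#' @param resolution_deg grid resolution (0.5, 1.0 or 4.0).
#' @param lon_range,lat_range domain extent in degrees (cell-aligned).
#' @param years analysis years.
#' @param gear_shares named percentages for the six gear classes, summing
#'   to 100.
#' @param purse_coastal_frac fraction of the purse-seine share assigned to
#'   the coastal purse fleet.
#' @param total_daily_effort expected vessel-days per day over the domain
#'   (before holiday/moratorium losses).
#' @param vessels_per_fleet synthetic vessels per fleet.
#' @param coastal_efold_km e-folding scale of the coastal fields, km.
#' @param coastal_max_km hard offshore limit of the coastal fields, km.
#' @param amplitude seasonal amplitude in `[0, 1]` (the maximum when
#'   `amplitude_field = "distance_ramp"`).
#' @param amplitude_field `"constant"`, or `"distance_ramp"` (amplitude
#'   grows linearly with distance to the nearest port, reaching
#'   `amplitude` at the farthest cell).
#' @param peak_field `"meridional"` (peak month cycles with the latitude
#'   row), `"cyclic"` (cycles with the cell index) or `"constant"`.
#' @param peak_month peak month used when `peak_field = "constant"`.
#' @param conserve_global renormalize the seasonal forcing so each
#'   fleet's global monthly total is unchanged (spatial redistribution
#'   only).
#' @param holiday_days named deficits in whole days for `dec`, `jan`,
#'   `feb`.
#' @param moratorium_windows named list (by year) of inclusive closure
#'   date ranges applying inside the EEZ band.
#' @param eez_lon longitude range of the EEZ band (spans all latitudes).
#' @param coast_lon longitude of the synthetic meridional coastline.
#' @param ports matrix of port (lon, lat) positions on the coast.
#' @param fine_resolution_deg resolution of the generated distance
#'   rasters.
#' @param noise `"poisson"` (vessel-day sampling), `"gaussian"`
#'   (multiplicative monthly noise of sd `noise_sd`) or `"none"`.
#' @param noise_sd sd of the gaussian noise mode, as a fraction of the
#'   cell's seasonal oscillation amplitude (`amp * base` level).
#' @param n_dropout extra vessels per fleet active in only the first
#'   year, to exercise the continuity filter.
#' @param seed integer random seed.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(resolution_deg = 1.0,
                               lon_range = c(0, 30),
                               lat_range = c(-12, 12),
                               years = 2015:2017,
                               gear_shares = c(trawlers = 53, fixed_gear = 15,
                                               drifting_longlines = 13,
                                               purse_seines = 11,
                                               squid_jigger = 4, other = 4),
                               purse_coastal_frac = 0.55,
                               total_daily_effort = 400,
                               vessels_per_fleet = 60L,
                               coastal_efold_km = 150,
                               coastal_max_km = 600,
                               amplitude = 0.6,
                               amplitude_field = c("constant", "distance_ramp"),
                               peak_field = c("meridional", "cyclic", "constant"),
                               peak_month = 6L,
                               conserve_global = TRUE,
                               holiday_days = c(dec = 4, jan = 4, feb = 2.5),
                               moratorium_windows = list(
                                 `2015` = c("2015-05-16", "2015-09-16"),
                                 `2016` = c("2016-05-16", "2016-09-16"),
                                 `2017` = c("2017-05-01", "2017-09-16")),
                               eez_lon = c(0, 4),
                               coast_lon = 0,
                               ports = cbind(lon = c(0, 0, 0),
                                             lat = c(-8, 0, 8)),
                               fine_resolution_deg = 0.1,
                               noise = c("poisson", "none", "gaussian"),
                               noise_sd = 0.05,
                               n_dropout = 0L,
                               seed = 1L) {
  amplitude_field <- match.arg(amplitude_field)
  peak_field <- match.arg(peak_field)
  noise <- match.arg(noise)
  grid <- grid_spec(resolution_deg)
  res <- grid$res
  stopifnot(length(lon_range) == 2L, length(lat_range) == 2L,
            diff(lon_range) > 0, diff(lat_range) > 0)
  if (any(abs(c(lon_range, lat_range) / res - round(c(lon_range, lat_range) / res)) > 1e-9)) {
    input_error("domain edges must be aligned to the grid resolution")
  }
  if (abs(sum(gear_shares) - 100) > 1e-6) input_error("gear shares must sum to 100")
  if (!all(sort(names(gear_shares)) == sort(GEAR_CLASSES))) {
    input_error("gear_shares must name exactly the six gear classes")
  }
  if (amplitude < 0 || amplitude > 1) input_error("amplitude must be in [0, 1]")
  if (eez_lon[1] < lon_range[1] || eez_lon[2] > lon_range[2]) {
    input_error("EEZ band must lie inside the domain")
  }
  if (is.null(ports) || nrow(as.matrix(ports)) == 0L) input_error("no ports specified")
  hol <- c(dec = 0, jan = 0, feb = 0)
  hol[names(holiday_days)] <- holiday_days
  p <- gear_shares["purse_seines"]
  fleet_shares <- c(trawlers = unname(gear_shares["trawlers"]),
                    fixed_gear = unname(gear_shares["fixed_gear"]),
                    drifting_longlines = unname(gear_shares["drifting_longlines"]),
                    purse_coastal = unname(p * purse_coastal_frac),
                    purse_high_seas = unname(p * (1 - purse_coastal_frac)),
                    squid_jigger = unname(gear_shares["squid_jigger"]),
                    other = unname(gear_shares["other"]))
  structure(list(
    grid = grid, lon_range = lon_range, lat_range = lat_range,
    years = as.integer(years),
    gear_shares = gear_shares, purse_coastal_frac = purse_coastal_frac,
    fleet_shares = fleet_shares,
    coastal_fleets = c("trawlers", "fixed_gear", "purse_coastal"),
    total_daily_effort = total_daily_effort,
    vessels_per_fleet = as.integer(vessels_per_fleet),
    coastal_efold_km = coastal_efold_km, coastal_max_km = coastal_max_km,
    amplitude = amplitude, amplitude_field = amplitude_field,
    peak_field = peak_field, peak_month = as.integer(peak_month),
    conserve_global = conserve_global,
    holiday_days = hol,
    moratorium_windows = lapply(moratorium_windows, as.IDate),
    eez_lon = eez_lon, coast_lon = coast_lon,
    ports = as.matrix(ports),
    fine_resolution_deg = fine_resolution_deg,
    noise = noise, noise_sd = noise_sd,
    n_dropout = as.integer(n_dropout),
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario: %.1f deg, lon [%g, %g], lat [%g, %g], %d-%d, %s noise, seed %d>\n",
              x$grid$res, x$lon_range[1], x$lon_range[2], x$lat_range[1],
              x$lat_range[2], min(x$years), max(x$years), x$noise, x$seed))
  invisible(x)
}

#' Domain cells of a scenario, with distances and EEZ membership
#'
#' @param scn a [synthetic_scenario()].
#' @return a `data.table` with `cell, lon, lat, row, col, dist_shore_km,
#'   dist_port_km, in_eez`.
#' @export
scenario_cells <- function(scn) {
  res <- scn$grid$res
  lon <- seq(scn$lon_range[1] + res / 2, scn$lon_range[2] - res / 2, by = res)
  lat <- seq(scn$lat_range[1] + res / 2, scn$lat_range[2] - res / 2, by = res)
  d <- CJ(lat = lat, lon = lon)[, .(lon, lat)]
  d[, cell := lonlat_to_cell(scn$grid, lon, lat)]
  d[, col := as.integer(round((lon - (scn$lon_range[1] + res / 2)) / res)) + 1L]
  d[, row := as.integer(round((lat - (scn$lat_range[1] + res / 2)) / res)) + 1L]
  d[, dist_shore_km := geosphere::distHaversine(cbind(lon, lat),
                                                cbind(scn$coast_lon, lat),
                                                r = EARTH_RADIUS_KM)]
  dp <- rep(Inf, nrow(d))
  for (k in seq_len(nrow(scn$ports))) {
    dp <- pmin(dp, geosphere::distHaversine(cbind(d$lon, d$lat),
                                            scn$ports[k, , drop = TRUE],
                                            r = EARTH_RADIUS_KM))
  }
  d[, dist_port_km := dp]
  d[, in_eez := lon >= scn$eez_lon[1] & lon < scn$eez_lon[2]]
  setkey(d, cell)
  d[]
}

#' Per-fleet spatial base fields, peak months and amplitudes
#'
#' The base field of a fleet gives its expected vessel-days per day per
#' cell before seasonal, holiday and moratorium modulation; fields are
#' normalized so each fleet's domain total matches its share of
#' `total_daily_effort`.
#'
#' @param scn a [synthetic_scenario()].
#' @param cells optional precomputed [scenario_cells()].
#' @return a `data.table` with `fleet, cell, base, peak, amp` plus the
#'   cell descriptors.
#' @export
scenario_fields <- function(scn, cells = scenario_cells(scn)) {
  out <- list()
  peak <- switch(scn$peak_field,
    meridional = ((cells$row - 1L) %% 12L) + 1L,
    cyclic = ((seq_len(nrow(cells)) - 1L) %% 12L) + 1L,
    constant = rep(scn$peak_month, nrow(cells)))
  amp <- switch(scn$amplitude_field,
    constant = rep(scn$amplitude, nrow(cells)),
    distance_ramp = scn$amplitude * cells$dist_port_km / max(cells$dist_port_km))
  for (f in names(scn$fleet_shares)) {
    w <- if (f %in% scn$coastal_fleets) {
      exp(-cells$dist_shore_km / scn$coastal_efold_km) *
        (cells$dist_shore_km <= scn$coastal_max_km)
    } else {
      rep(1, nrow(cells))
    }
    base <- w / sum(w) * scn$fleet_shares[[f]] / 100 * scn$total_daily_effort
    out[[f]] <- data.table(fleet = f, cells, base = base, peak = peak, amp = amp)
  }
  rbindlist(out)
}

# inclusive closure window for a year, or NULL
closure_window <- function(scn, year) {
  scn$moratorium_windows[[as.character(year)]]
}

# days of month (y, m) on which an EEZ cell is open to fishing
open_days <- function(scn, year, month, in_eez) {
  nd <- days_in_month(year, month)
  dd <- seq_len(nd)
  if (!in_eez) return(dd)
  w <- closure_window(scn, year)
  if (is.null(w)) return(dd)
  dates <- as.IDate(sprintf("%04d-%02d-%02d", year, month, dd))
  dd[dates < w[1] | dates > w[2]]
}

# full expected-effort table: fleet, cell, year, month, days, e (expected
# vessel-days per day), in_eez
expected_table <- function(scn) {
  cells <- scenario_cells(scn)
  fields <- scenario_fields(scn, cells)
  base <- fields[, .(fleet, cell, base, peak, amp, in_eez)]
  nb <- nrow(base)
  seas <- base[rep(seq_len(nb), times = 12L)]
  seas[, month := rep(1:12, each = nb)]
  seas[, s := 1 + amp * cos(2 * pi * (month - peak) / 12)]
  if (scn$conserve_global) {
    # normalize over the open-ocean (non-EEZ) cells: seasonal forcing
    # redistributes deployment there without changing its monthly total,
    # while the EEZ band is dominated by the moratorium anyway
    ref <- if (any(!seas$in_eez)) seas[in_eez == FALSE] else seas
    norm <- ref[, .(nf = sum(base) / sum(base * s)), by = .(fleet, month)]
    seas <- norm[seas, on = c("fleet", "month")]
    seas[, s := s * nf]
  }
  seas[, e0 := base * s]
  seas <- seas[, .(fleet, cell, month, e0, base, amp, in_eez)]
  ny <- length(scn$years)
  out <- seas[rep(seq_len(.N), times = ny)]
  out[, year := rep(as.integer(scn$years), each = nrow(seas))]
  out[, days := days_in_month(year, month)]
  hol <- fifelse(out$month == 12L, scn$holiday_days[["dec"]],
         fifelse(out$month == 1L, scn$holiday_days[["jan"]],
         fifelse(out$month == 2L, scn$holiday_days[["feb"]], 0)))
  out[, hol_factor := 1 - hol / days]
  open_frac <- CJ(year = as.integer(scn$years), month = 1:12,
                  in_eez = c(TRUE, FALSE))
  open_frac[, frac := mapply(function(y, m, z)
    length(open_days(scn, y, m, z)) / days_in_month(y, m),
    year, month, in_eez)]
  out <- open_frac[out, on = c("year", "month", "in_eez")]
  out[, e := e0 * hol_factor * frac]
  setorder(out, fleet, cell, year, month)
  out[, .(fleet, cell, year, month, days, e, base, amp, in_eez)]
}

#' Expected (noise-free) monthly effort of a scenario
#'
#' @param scn a [synthetic_scenario()].
#' @return a fleet-labelled [monthly_effort_grid()] of expectations.
#' @export
expected_monthly_effort <- function(scn) {
  et <- expected_table(scn)
  monthly_effort_grid(et[, .(gear = fleet, year, month, cell, effort = e)],
                      scn$grid, months = month_table(scn$years),
                      gears = names(scn$fleet_shares))
}

#' Simulate a monthly effort grid from a scenario
#'
#' Applies the scenario's noise model at the monthly level: Poisson
#' vessel-day counts around the expectation (then divided back by the
#' days in the month), multiplicative gaussian noise, or none.
#'
#' @param scn a [synthetic_scenario()].
#' @param seed overrides the scenario seed.
#' @return a fleet-labelled [monthly_effort_grid()].
#' @export
simulate_monthly <- function(scn, seed = scn$seed) {
  et <- expected_table(scn)
  set.seed(seed)
  # gaussian noise is scaled by the cell's seasonal oscillation amplitude
  # (amp * base level), the natural unit for seasonality-recovery
  # experiments ("noise at x% of amplitude")
  eff <- switch(scn$noise,
    none = et$e,
    poisson = rpois(nrow(et), et$e * et$days) / et$days,
    gaussian = pmax(0, et$e + rnorm(nrow(et), 0, scn$noise_sd * et$amp * et$base)))
  monthly_effort_grid(et[, .(gear = fleet, year, month, cell, effort = eff)],
                      scn$grid, months = month_table(scn$years),
                      gears = names(scn$fleet_shares))
}

#' Ground truth of a scenario
#'
#' Collects everything needed by recovery tests: injected peak months and
#' amplitudes per cell, expected gear/fleet shares (integrating the
#' holiday and moratorium losses), expected monthly effort totals, holiday
#' deficits and EEZ cells.
#'
#' @param scn a [synthetic_scenario()].
#' @return a list.
#' @export
scenario_truth <- function(scn) {
  et <- expected_table(scn)
  fields <- scenario_fields(scn)
  # same definition as gear_shares(): window sum of the daily-mean series
  sh <- et[, .(S = sum(e)), by = fleet]
  shares <- 100 * sh$S / sum(sh$S)
  names(shares) <- sh$fleet
  # realized peak: argmax (earliest on ties) of the expected all-fleet
  # climatological profile -- differs from the cosine phase where holiday
  # or moratorium forcing reshapes the annual cycle
  clim <- et[, .(e_n = sum(e)), by = .(cell, month)]
  realized <- clim[order(cell, month),
                   .(expected_peak = month[which.max(e_n)]), by = cell]
  pk <- unique(fields[, .(cell, peak, amp)])
  pk <- realized[pk, on = "cell"]
  list(
    expected_fleet_shares = shares[names(scn$fleet_shares)],
    expected_vessel_days = et[, sum(e * days)],
    peak = pk[, .(cell, peak, amp, expected_peak)],
    holiday_days = scn$holiday_days,
    moratorium_windows = scn$moratorium_windows,
    eez_cells = scenario_cells(scn)[in_eez == TRUE, cell],
    seed = scn$seed
  )
}

#' Generate vessel-resolved fishing records from a scenario
#'
#' Draws Poisson (or deterministically rounded, when `noise = "none"`)
#' vessel-day counts per fleet, cell and month, spreads them uniformly
#' over the month's open days, and assigns them to distinct synthetic
#' vessels of the fleet. Every regular vessel is guaranteed at least one
#' record per calendar year (by relabelling records of busy fleet-mates
#' when needed), so the continuity filter keeps all of them; `n_dropout`
#' extra vessels per fleet appear only in the first year to exercise the
#' filter. Vessel lengths and the mean shore distance of each vessel's
#' fishing positions are reported so the purse-seine split can be
#' recovered.
#'
#' @param scn a [synthetic_scenario()].
#' @return a list with `vessels` (vessel table including
#'   `mean_shore_distance_nm`), `records` (`vessel_id, date, lat, lon,
#'   is_fishing`), and `truth` ([scenario_truth()] plus the fleet of every
#'   vessel and record counts).
#' @export
generate_parametric <- function(scn) {
  set.seed(scn$seed)
  et <- expected_table(scn)
  cells <- scenario_cells(scn)
  nv <- scn$vessels_per_fleet
  fleets <- names(scn$fleet_shares)

  counts <- if (scn$noise == "poisson") rpois(nrow(et), et$e * et$days)
            else as.integer(round(et$e * et$days))
  rows <- et[counts > 0][, count := counts[counts > 0]]
  ex <- rows[rep(seq_len(.N), count)]
  # uniform day within the month's open days (closure days excluded)
  ex[, day := {
    od <- open_days(scn, year[1], month[1], in_eez[1])
    od[sample.int(length(od), .N, replace = TRUE)]
  }, by = .(year, month, in_eez)]
  # distinct vessels within each (fleet, cell, date)
  ex[, grp_n := .N, by = .(fleet, cell, year, month, day)]
  if (nrow(ex[grp_n > nv])) {
    input_error("cell-day counts exceed the vessel pool; increase vessels_per_fleet")
  }
  ex[grp_n == 1L, vidx := sample.int(nv, .N, replace = TRUE)]
  ex[grp_n > 1L, vidx := sample(nv, .N),
     by = .(fleet, cell, year, month, day)]
  # continuity patch: give every vessel at least one record per year by
  # relabelling records of the busiest fleet-mates
  for (f in fleets) {
    for (y in scn$years) {
      sel <- which(ex$fleet == f & ex$year == y)
      if (!length(sel)) next
      cnt <- tabulate(ex$vidx[sel], nbins = nv)
      missing <- which(cnt == 0L)
      for (mv in missing) {
        donor <- which.max(cnt)
        if (cnt[donor] < 2L) break  # not enough records to spread
        ridx <- sel[which(ex$vidx[sel] == donor)[1]]
        ex[ridx, vidx := mv]
        cnt[donor] <- cnt[donor] - 1L
        cnt[mv] <- 1L
      }
    }
  }
  fleet_code <- toupper(substr(gsub("_", "", fleets), 1, 3))
  names(fleet_code) <- fleets
  ex[, vessel_id := sprintf("%s%02d_%03d", fleet_code[fleet],
                            match(fleet, fleets), vidx)]
  ex <- cells[, .(cell, lon, lat, dist_shore_km)][ex, on = "cell"]
  res <- scn$grid$res
  ex[, `:=`(
    date = as.IDate(sprintf("%04d-%02d-%02d", year, month, day)),
    lon_pos = lon + runif(.N, -0.4995, 0.4995) * res,
    lat_pos = lat + runif(.N, -0.4995, 0.4995) * res
  )]

  # vessel table
  len_range <- list(trawlers = c(20, 60), fixed_gear = c(15, 40),
                    drifting_longlines = c(30, 70), purse_coastal = c(20, 35),
                    purse_high_seas = c(45, 80), squid_jigger = c(30, 60),
                    other = c(15, 50))
  vt <- rbindlist(lapply(fleets, function(f) {
    data.table(vessel_id = sprintf("%s%02d_%03d", fleet_code[f],
                                   match(f, fleets), seq_len(nv)),
               fleet = f,
               gear_class = if (f %in% c("purse_coastal", "purse_high_seas"))
                 "purse_seines" else f,
               length_m = round(runif(nv, len_range[[f]][1], len_range[[f]][2]), 1))
  }))
  shore <- ex[, .(mean_shore_distance_nm = mean(dist_shore_km) / KM_PER_NM),
              by = vessel_id]
  vt <- shore[vt, on = "vessel_id"]

  records <- ex[, .(vessel_id, date, lat = lat_pos, lon = lon_pos,
                    is_fishing = 1L)]

  # dropout vessels: active only in the first year
  n_dropout_records <- 0L
  if (scn$n_dropout > 0L) {
    drop_vt <- rbindlist(lapply(fleets, function(f) {
      data.table(vessel_id = sprintf("DROP_%s%02d_%03d", fleet_code[f],
                                     match(f, fleets), seq_len(scn$n_dropout)),
                 fleet = f,
                 gear_class = if (f %in% c("purse_coastal", "purse_high_seas"))
                   "purse_seines" else f,
                 length_m = round(runif(scn$n_dropout, len_range[[f]][1],
                                        len_range[[f]][2]), 1),
                 mean_shore_distance_nm = NA_real_)
    }))
    pick <- cells[sample.int(nrow(cells), nrow(drop_vt), replace = TRUE)]
    drop_rec <- data.table(vessel_id = drop_vt$vessel_id,
                           date = as.IDate(sprintf("%04d-06-15", scn$years[1])),
                           lat = pick$lat, lon = pick$lon, is_fishing = 1L)
    n_dropout_records <- nrow(drop_rec)
    records <- rbind(records, drop_rec)
    vt <- rbind(vt, drop_vt[, names(vt), with = FALSE])
  }
  setorder(records, vessel_id, date, lon, lat)

  truth <- scenario_truth(scn)
  truth$fleet_of_vessel <- vt[, .(vessel_id, fleet)]
  truth$n_records <- nrow(records) - n_dropout_records
  truth$n_dropout_records <- n_dropout_records
  list(vessels = vt[, .(vessel_id, gear_class, length_m, mean_shore_distance_nm)],
       records = records,
       truth = truth)
}

#' Synthetic distance rasters to the nearest port and to shore
#'
#' Exact great-circle (haversine, R = 6371 km) distances on a fine
#' regular grid over the scenario domain: to the nearest of the
#' scenario's ports, and to the meridional coastline.
#'
#' @param scn a [synthetic_scenario()].
#' @return a list with `port` and `shore` [distance_raster()]s.
#' @export
generate_distance_fields <- function(scn) {
  if (nrow(scn$ports) == 0L) input_error("no ports specified")
  dlon <- seq(scn$lon_range[1], scn$lon_range[2], by = scn$fine_resolution_deg)
  dlat <- seq(scn$lat_range[1], scn$lat_range[2], by = scn$fine_resolution_deg)
  pts <- CJ(lat = dlat, lon = dlon)[, .(lon, lat)]
  dp <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(scn$ports))) {
    dp <- pmin(dp, geosphere::distHaversine(cbind(pts$lon, pts$lat),
                                            scn$ports[k, , drop = TRUE],
                                            r = EARTH_RADIUS_KM))
  }
  ds <- geosphere::distHaversine(cbind(pts$lon, pts$lat),
                                 cbind(scn$coast_lon, pts$lat),
                                 r = EARTH_RADIUS_KM)
  # pts is ordered lat-major with lon varying fastest, matching
  # column-major fill of an nlon x nlat matrix
  port <- distance_raster(dlon, dlat, matrix(dp, length(dlon), length(dlat)))
  shore <- distance_raster(dlon, dlat, matrix(ds, length(dlon), length(dlat)))
  list(port = port, shore = shore)
}

#' Synthetic EEZ mask and polygon
#'
#' The EEZ is the scenario's coastal longitude band over the full
#' latitude extent of the domain; membership on the grid follows the
#' center-in-polygon rule.
#'
#' @param scn a [synthetic_scenario()].
#' @param path optional path to also write the polygon as GeoJSON.
#' @return a list with `mask` (a [cell_mask()]) and `polygon` (the vertex
#'   matrix).
#' @export
generate_eez_mask <- function(scn, path = NULL) {
  poly <- rbind(c(scn$eez_lon[1], scn$lat_range[1]),
                c(scn$eez_lon[2], scn$lat_range[1]),
                c(scn$eez_lon[2], scn$lat_range[2]),
                c(scn$eez_lon[1], scn$lat_range[2]))
  mask <- mask_from_polygon(poly, scn$grid, label = "synthetic EEZ")
  if (!is.null(path)) {
    write_geojson_polygon(poly, path, properties = list(label = "synthetic EEZ"))
  }
  list(mask = mask, polygon = poly)
}
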