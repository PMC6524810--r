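# Bioeconomic effort dynamics: effort in each cell grows with profit per
# unit effort and is removed by regulation,
#   dE/dt = kappa_e * (p * q(t) * B(t) - c) * E - R(t, cell),  E >= 0,
# with harvest H = q E B. Catchability and biomass may be seasonally
# forced; the regulation term is nonzero inside a closure region during
# closure windows. All rates are per day.

#' Parameterize the bioeconomic effort simulator
#'
#' @param kappa_e effort responsiveness (per $ per day).
#' @param price ex-vessel price p, $/kg.
#' @param cost cost per unit effort c, $/fishing-day.
#' @param q0 mean catchability, km^2/fishing-day.
#' @param q_amp relative seasonal amplitude of q in `[0, 1]`.
#' @param B0 mean biomass density, kg/km^2.
#' @param B_amp relative seasonal amplitude of B in `[0, 1]`.
#' @param peak_month month at which the q and B forcings peak.
#' @param E0 initial effort (fishing-days/day per cell; scalar or one
#'   value per cell).
#' @param R_rate regulatory effort removal inside the closure
#'   (fishing-days/day^2), applied to closure-region cells during closure
#'   windows; 0 elsewhere.
#' @return an object of class `bioeconomic_params`.
#' @export
bioeconomic_params <- function(kappa_e = 0.002, price = 1.5, cost = 1.0,
                               q0 = 1.0, q_amp = 0, B0 = 1.0, B_amp = 0,
                               peak_month = 6L, E0 = 1.0, R_rate = 0) {
  vals <- c(kappa_e, price, cost, q0, q_amp, B0, B_amp, E0, R_rate)
  if (!all(is.finite(vals))) input_error("non-finite bioeconomic parameter")
  if (any(c(q_amp, B_amp) < 0) || any(c(q_amp, B_amp) > 1)) {
    input_error("seasonal amplitudes must be in [0, 1]")
  }
  if (R_rate < 0) input_error("R_rate must be nonnegative")
  structure(list(kappa_e = kappa_e, price = price, cost = cost, q0 = q0,
                 q_amp = q_amp, B0 = B0, B_amp = B_amp,
                 peak_month = as.integer(peak_month), E0 = E0,
                 R_rate = R_rate), class = "bioeconomic_params")
}

# fractional month (1..13) of a date, for smooth seasonal forcing
month_phase <- function(date) {
  y <- data.table::year(date); m <- data.table::month(date)
  m + (data.table::mday(date) - 1) / days_in_month(y, m)
}

#' Simulate bioeconomic effort dynamics over a scenario domain
#'
#' Daily explicit-Euler integration of the effort equation in every
#' domain cell, with effort clipped at zero. Regulation `R_rate` acts on
#' cells of the scenario's EEZ band during the scenario's moratorium
#' windows.
#'
#' @param params a [bioeconomic_params()].
#' @param scn a [synthetic_scenario()] providing the grid, domain, years
#'   and closure geometry.
#' @param dt_days Euler step in days (default 1).
#' @return a list with `daily` (`cell, date, E`), `monthly` (a
#'   [monthly_effort_grid()] labelled gear `"bioeconomic"`, mean daily
#'   effort per month) and `params`.
#' @export
simulate_bioeconomic <- function(params, scn, dt_days = 1) {
  stopifnot(inherits(params, "bioeconomic_params"),
            inherits(scn, "synthetic_scenario"))
  cells <- scenario_cells(scn)
  nc <- nrow(cells)
  dates <- seq(as.IDate(sprintf("%04d-01-01", min(scn$years))),
               as.IDate(sprintf("%04d-12-31", max(scn$years))), by = 1L)
  E <- rep_len(params$E0, nc)
  closed_on <- function(date) {
    w <- closure_window(scn, data.table::year(date))
    !is.null(w) && date >= w[1] && date <= w[2]
  }
  out <- matrix(0, nc, length(dates))
  for (k in seq_along(dates)) {
    ph <- month_phase(dates[k])
    qt <- params$q0 * (1 + params$q_amp * cos(2 * pi * (ph - params$peak_month) / 12))
    Bt <- params$B0 * (1 + params$B_amp * cos(2 * pi * (ph - params$peak_month) / 12))
    R <- if (closed_on(dates[k])) params$R_rate * cells$in_eez else rep(0, nc)
    growth <- params$kappa_e * (params$price * qt * Bt - params$cost)
    E <- pmax(0, E + dt_days * (growth * E - R))
    out[, k] <- E
  }
  daily <- data.table(cell = rep(cells$cell, length(dates)),
                      date = rep(dates, each = nc),
                      E = as.vector(out))
  daily[, `:=`(year = data.table::year(date), month = data.table::month(date))]
  monthly <- daily[, .(effort = mean(E)), by = .(cell, year, month)]
  monthly[, gear := "bioeconomic"]
  meg <- monthly_effort_grid(monthly[, .(gear, year, month, cell, effort)],
                             scn$grid, months = month_table(scn$years),
                             gears = "bioeconomic")
  list(daily = daily[, .(cell, date, E)], monthly = meg, params = params)
}

#' Emit vessel-day records from simulated bioeconomic effort
#'
#' Thins the daily effort field into integer vessel-day counts (Poisson)
#' and returns a record stream in the standard format, assigned to a pool
#' of synthetic vessels.
#'
#' @param sim a [simulate_bioeconomic()] result.
#' @param scn the [synthetic_scenario()] used for the simulation.
#' @param gear_class gear label for the emitted vessels.
#' @param n_vessels vessel pool size.
#' @param seed random seed.
#' @return a list with `vessels` and `records` in the ingest formats.
#' @export
bioeconomic_records <- function(sim, scn, gear_class = "trawlers",
                                n_vessels = 100L, seed = scn$seed) {
  set.seed(seed)
  d <- sim$daily[E > 0]
  d[, n := rpois(.N, E)]
  d <- d[n > 0]
  if (nrow(d) && max(d$n) > n_vessels) {
    input_error("daily counts exceed the vessel pool; increase n_vessels")
  }
  ex <- d[rep(seq_len(.N), n)]
  ex[, grp_n := .N, by = .(cell, date)]
  ex[grp_n == 1L, vidx := sample.int(n_vessels, .N, replace = TRUE)]
  ex[grp_n > 1L, vidx := sample(n_vessels, .N), by = .(cell, date)]
  ctr <- cell_center(scn$grid, ex$cell)
  res <- scn$grid$res
  records <- data.table(
    vessel_id = sprintf("BIO_%03d", ex$vidx),
    date = ex$date,
    lat = ctr$lat + runif(nrow(ex), -0.4995, 0.4995) * res,
    lon = ctr$lon + runif(nrow(ex), -0.4995, 0.4995) * res,
    is_fishing = 1L)
  setorder(records, vessel_id, date)
  vessels <- data.table(vessel_id = sprintf("BIO_%03d", seq_len(n_vessels)),
                        gear_class = gear_class,
                        length_m = round(runif(n_vessels, 20, 60), 1),
                        mean_shore_distance_nm = NA_real_)
  list(vessels = vessels, records = records)
}
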