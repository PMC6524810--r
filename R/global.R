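# Gear-stratified global effort series, relative variation, gear shares
# and the implied winter-holiday day estimator.

#' Globally integrated monthly effort by gear
#'
#' Sums the monthly local effort over all cells, giving E_g(month) in
#' fishing-vessel-days per day for every gear/fleet and month of the
#' window (zero for gear-months with no effort). The total E = sum_g E_g.
#'
#' @param meg a [monthly_effort_grid()] (optionally masked first with
#'   [apply_mask()]).
#' @return an object of class `global_gear_series`: a list with `data`
#'   (`gear, year, month, E`), `months` and `gears`.
#' @export
global_series <- function(meg) {
  stopifnot(inherits(meg, "monthly_effort_grid"))
  full <- CJ(gear = meg$gears, year = meg$months$year, month = 1:12, unique = TRUE)
  full <- full[meg$months, on = c("year", "month"), nomatch = NULL]
  agg <- meg$data[, .(E = sum(effort)), by = .(gear, year, month)]
  out <- agg[full[, .(gear, year, month)], on = c("gear", "year", "month")]
  out[is.na(E), E := 0]
  setkey(out, gear, year, month)
  structure(list(data = out[], months = copy(meg$months), gears = meg$gears),
            class = "global_gear_series")
}

#' @export
print.global_gear_series <- function(x, ...) {
  cat(sprintf("<global_gear_series: %d gears x %d months>\n",
              length(x$gears), nrow(x$months)))
  invisible(x)
}

#' Total effort series over all gears
#'
#' @param series a [global_series()] result.
#' @return a `data.table` with `year`, `month`, `days`, `E` (summed over gears).
#' @export
total_series <- function(series) {
  tot <- series$data[, .(E = sum(E)), by = .(year, month)]
  out <- tot[series$months, on = c("year", "month")]
  setkey(out, year, month)
  out[, .(year, month, days, E)]
}

#' Relative variation of global effort per gear
#'
#' Divides each gear's monthly series by its full-window mean and reports
#' the sample standard deviation of the relative series, the indicator of
#' the intensity of the seasonal cycle. Gears with zero mean effort are
#' excluded with a warning.
#'
#' @param series a [global_series()] result (needs at least 2 months).
#' @return a list with `data` (`gear, year, month, rel`), `sd`
#'   (`gear, sd_rel`) and `excluded` (character).
#' @export
relative_variation <- function(series) {
  stopifnot(inherits(series, "global_gear_series"))
  if (nrow(series$months) < 2L) input_error("need at least 2 months")
  d <- copy(series$data)
  means <- d[, .(Ebar = mean(E)), by = gear]
  excluded <- means[Ebar <= 0, gear]
  if (length(excluded)) {
    warning("gear(s) with zero mean effort excluded from relative variation: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  d <- d[means, on = "gear"][Ebar > 0]
  d[, rel := E / Ebar]
  sds <- d[, .(sd_rel = sd(rel)), by = gear]
  list(data = d[, .(gear, year, month, rel)], sd = sds, excluded = excluded)
}

#' Percentage share of each gear in the window-summed effort
#'
#' @param series a [global_series()] result.
#' @return a named numeric vector of percentages summing to 100.
#' @export
gear_shares <- function(series) {
  stopifnot(inherits(series, "global_gear_series"))
  tot <- series$data[, .(S = sum(E)), by = gear]
  if (sum(tot$S) <= 0) input_error("zero total effort; shares undefined")
  shares <- 100 * tot$S / sum(tot$S)
  names(shares) <- tot$gear
  shares[series$gears]
}

#' Implied holiday days from the boreal-winter effort deficit
#'
#' The baseline is the mean total monthly (daily-mean) effort over all
#' March--November months of the window; for each target month m the
#' implied number of holiday days is `(1 - E_m / baseline) * days(m)`,
#' computed per year with that year's month length and then averaged per
#' calendar month. Values are signed: a busier-than-baseline month yields
#' negative days. The series should be computed after removing the
#' moratorium-affected EEZ.
#'
#' @param series a [global_series()] result (typically on masked effort).
#' @param target_months calendar months to estimate (default Dec, Jan, Feb).
#' @param baseline_months calendar months defining the baseline (default
#'   March through November).
#' @return an object of class `holiday_estimate`: a list with `baseline`
#'   (vessel-days per day) and `estimates`
#'   (`month, E_mean, implied_days`).
#' @export
implied_holiday_days <- function(series, target_months = c(12L, 1L, 2L),
                                 baseline_months = 3:11) {
  stopifnot(inherits(series, "global_gear_series"))
  tot <- total_series(series)
  base <- tot[month %in% baseline_months, mean(E)]
  if (!is.finite(base) || base <= 0) input_error("holiday baseline is zero")
  tm <- tot[month %in% target_months]
  tm[, implied := (1 - E / base) * days]
  est <- tm[, .(E_mean = mean(E), implied_days = mean(implied)), by = month]
  est <- est[order(match(month, target_months))]
  structure(list(baseline = base, estimates = est[]), class = "holiday_estimate")
}

#' @export
print.holiday_estimate <- function(x, ...) {
  cat(sprintf("Baseline (Mar-Nov mean total effort): %.3f vessel-days/day\n",
              x$baseline))
  for (i in seq_len(nrow(x$estimates))) {
    cat(sprintf("  month %2d: %.1f implied holiday days\n",
                x$estimates$month[i], x$estimates$implied_days[i]))
  }
  invisible(x)
}
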