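library(data.table)

# Build a monthly effort grid from per-cell monthly profiles.
# `profiles`: matrix (n_cells x 12, recycled across years) or
# (n_cells x 12*n_years); rows are cells, columns months in order.
make_meg <- function(profiles, years = 2015:2017, gear = "trawlers",
                     resolution = 1, cells = NULL) {
  profiles <- rbind(profiles)
  grid <- grid_spec(resolution)
  ny <- length(years)
  if (ncol(profiles) == 12L) {
    profiles <- profiles[, rep(1:12, ny), drop = FALSE]
  }
  stopifnot(ncol(profiles) == 12L * ny)
  cells <- cells %||% seq_len(nrow(profiles))
  dt <- data.table(
    cell = rep(cells, each = 12L * ny),
    year = rep(rep(years, each = 12L), nrow(profiles)),
    month = rep(rep(1:12, ny), nrow(profiles)),
    effort = as.vector(t(profiles)),
    gear = gear
  )
  monthly_effort_grid(dt, grid, months = effortseas:::month_table(years))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-gear, one-cell series with given monthly daily-mean efforts
make_series <- function(monthly_effort, years = 2015) {
  meg <- make_meg(rbind(monthly_effort), years = years)
  global_series(meg)
}

# random fishing records over a handful of cells / vessels
random_records <- function(n = 200, n_vessels = 5, seed = 1,
                           dates = seq(as.IDate("2015-01-01"),
                                       as.IDate("2015-03-31"), by = 1)) {
  set.seed(seed)
  data.table(
    vessel_id = sprintf("V%02d", sample.int(n_vessels, n, replace = TRUE)),
    date = sample(dates, n, replace = TRUE),
    lat = runif(n, 0, 4),
    lon = runif(n, 0, 4)
  )
}

simple_vessels <- function(ids, gear = "trawlers") {
  data.table(vessel_id = ids, gear_class = gear, length_m = 30,
             mean_shore_distance_nm = NA_real_)
}

# small fast scenario for end-to-end tests (overridable defaults)
tiny_scenario <- function(...) {
  args <- list(lon_range = c(0, 8), lat_range = c(-4, 4),
               total_daily_effort = 60, vessels_per_fleet = 25L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_scenario, args)
}
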