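test_that("scenario validation rejects infeasible parameterizations", {
  expect_error(synthetic_scenario(gear_shares = c(trawlers = 90, fixed_gear = 20,
                                                  drifting_longlines = 0,
                                                  purse_seines = 0,
                                                  squid_jigger = 0, other = 0)),
               "sum to 100")
  expect_error(synthetic_scenario(amplitude = 1.5), "amplitude")
  expect_error(synthetic_scenario(eez_lon = c(-10, 4)), "inside the domain")
  expect_error(synthetic_scenario(ports = cbind(lon = numeric(0),
                                                lat = numeric(0))), "ports")
})

test_that("identical scenarios and seeds generate identical records", {
  scn <- tiny_scenario(seed = 5)
  a <- generate_parametric(scn)
  b <- generate_parametric(scn)
  expect_identical(a$records, b$records)
  expect_identical(a$vessels, b$vessels)
  c <- generate_parametric(tiny_scenario(seed = 6))
  expect_false(identical(a$records, c$records))
})

test_that("a flat scenario yields zero seasonality everywhere downstream", {
  scn <- tiny_scenario(amplitude = 0, holiday_days = c(dec = 0, jan = 0, feb = 0),
                       moratorium_windows = list(), noise = "none")
  si <- seasonality_index(climatology(expected_monthly_effort(scn)))
  expect_lt(max(si$data$si), 1e-9)
})

test_that("injected holiday deficits appear exactly in the noise-free expectation", {
  scn <- synthetic_scenario(noise = "none")
  meg <- expected_monthly_effort(scn)
  eez <- generate_eez_mask(scn)$mask
  tot <- total_series(global_series(apply_mask(meg, eez, "remove")))
  base <- tot[month %in% 3:11, mean(E)]
  expect_equal(tot[month == 12, unique(E)], base * (1 - 4 / 31),
               tolerance = 1e-9)
  expect_equal(tot[year == 2016 & month == 2, E], base * (1 - 2.5 / 29),
               tolerance = 1e-9)
  # and the estimator inverts the construction
  hol <- implied_holiday_days(global_series(apply_mask(meg, eez, "remove")))
  expect_equal(hol$estimates$implied_days, c(4, 4, 2.5), tolerance = 1e-9)
})

test_that("the moratorium zeroes EEZ effort during the closure windows", {
  scn <- synthetic_scenario(noise = "none")
  meg <- expected_monthly_effort(scn)
  eez <- generate_eez_mask(scn)$mask
  inz <- apply_mask(meg, eez, "keep")
  tot <- total_series(global_series(inz))
  # June-August fall entirely inside every closure window
  expect_true(all(tot[month %in% 6:8, E] == 0))
  expect_true(all(tot[month %in% c(3, 10), E] > 0))
  # 2017 closes from May 1st: the whole of May is lost that year only
  expect_equal(tot[year == 2017 & month == 5, E], 0)
  expect_gt(tot[year == 2015 & month == 5, E], 0)
})

test_that("Poisson monthly simulation is unbiased around the expectation", {
  scn <- tiny_scenario()
  et <- effortseas:::expected_table(scn)
  exp_vd <- sum(et$e * et$days)
  n_seeds <- 12
  vds <- sapply(seq_len(n_seeds), function(s)
    total_vessel_days(simulate_monthly(scn, seed = s)))
  # total vessel-days: Poisson sum, so variance = mean
  se <- sqrt(exp_vd / n_seeds)
  expect_lt(abs(mean(vds) - exp_vd), 3 * se)
})

test_that("generated records pass the continuity filter and conserve vessel-days", {
  scn <- tiny_scenario(seed = 2, n_dropout = 3L)
  sim <- generate_parametric(scn)
  rec <- filter_continuous_vessels(sim$records, scn$years)
  cont <- attr(rec, "continuity")
  expect_equal(cont$dropped, 3L * 7L)  # exactly the dropout vessels
  expect_equal(nrow(rec), sim$truth$n_records)
  vt <- split_purse_seiners(sim$vessels)
  daily <- rasterize_daily(rec, vt, scn$grid)
  expect_equal(sum(daily$n), sim$truth$n_records)
  meg <- monthly_aggregate(daily, scn$grid,
                           coverage = as.IDate(c("2015-01-01", "2017-12-31")))
  expect_equal(total_vessel_days(meg), sim$truth$n_records)
})

test_that("the purse-seine split recovers the generated fleets exactly", {
  sim <- generate_parametric(tiny_scenario(seed = 4))
  vt <- split_purse_seiners(sim$vessels)
  m <- merge(vt[, .(vessel_id, fleet)], sim$truth$fleet_of_vessel,
             by = "vessel_id", suffixes = c("_est", "_true"))
  expect_equal(m$fleet_est, m$fleet_true)
})

test_that("synthetic distance fields are exact haversine distances", {
  scn <- tiny_scenario(ports = cbind(lon = 2, lat = 0), fine_resolution_deg = 0.5)
  fields <- generate_distance_fields(scn)
  # zero at the port node
  i <- match(2, fields$port$lon); j <- match(0, fields$port$lat)
  expect_equal(fields$port$values[i, j], 0)
  # one degree along the equator is 2*pi*6371/360 km
  i1 <- match(3, fields$port$lon)
  expect_equal(fields$port$values[i1, j], 2 * pi * 6371 / 360, tolerance = 1e-6)
  # two ports: the field is the pointwise minimum of single-port fields
  scn2 <- tiny_scenario(ports = cbind(lon = c(2, 6), lat = c(0, 2)),
                        fine_resolution_deg = 0.5)
  scnB <- tiny_scenario(ports = cbind(lon = 6, lat = 2), fine_resolution_deg = 0.5)
  f2 <- generate_distance_fields(scn2)$port$values
  fA <- fields$port$values
  fB <- generate_distance_fields(scnB)$port$values
  expect_equal(f2, pmin(fA, fB), tolerance = 1e-9)
  # shore distance vanishes on the coastline meridian
  expect_true(all(fields$shore$values[match(0, fields$shore$lon), ] == 0))
})

test_that("the antipode of a port is half the Earth's circumference away", {
  scn <- synthetic_scenario(lon_range = c(0, 180), lat_range = c(-4, 4),
                            eez_lon = c(0, 4),
                            ports = cbind(lon = 0, lat = 0),
                            fine_resolution_deg = 4)
  f <- generate_distance_fields(scn)$port
  expect_equal(f$values[match(180, f$lon), match(0, f$lat)],
               pi * 6371, tolerance = 1e-3)
})

test_that("the EEZ mask covers the coastal band and round-trips as GeoJSON", {
  scn <- synthetic_scenario()
  f <- withr::local_tempfile(fileext = ".geojson")
  eez <- generate_eez_mask(scn, path = f)
  expect_length(eez$mask$cells, 4L * 24L)  # 4-degree band, 24 rows
  back <- read_mask(f, scn$grid)
  expect_equal(back$cells, eez$mask$cells)
  expect_equal(sort(eez$mask$cells),
               sort(scenario_cells(scn)[in_eez == TRUE, cell]))
})

test_that("gear shares of simulated data match the scenario truth", {
  scn <- synthetic_scenario(seed = 3)
  tr <- scenario_truth(scn)
  # noise-free: exact by construction
  sh0 <- gear_shares(global_series(expected_monthly_effort(scn)))
  expect_equal(unname(sh0), unname(tr$expected_fleet_shares[names(sh0)]),
               tolerance = 1e-9)
  # Poisson: close, at the sampling-error scale
  sh1 <- gear_shares(global_series(simulate_monthly(scn, seed = 8)))
  expect_lt(max(abs(sh1 - tr$expected_fleet_shares[names(sh1)])), 1)
})
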