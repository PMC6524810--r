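test_that("vessel tables parse, with unknown gears mapped to other", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,gear_class,length_m",
               "V1,trawlers,35",
               "V2,dredge,20",
               "V3,purse_seines,"), f)
  expect_warning(vt <- read_vessel_table(f), "other")
  expect_equal(vt$gear_class, c("trawlers", "other", "purse_seines"))
  expect_equal(vt$length_m, c(35, 20, NA))
  expect_true(all(is.na(vt$mean_shore_distance_nm)))
})

test_that("vessel tables without mandatory columns or rows fail loudly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("boat,gear_class,length_m", "V1,trawlers,35"), f)
  expect_error(read_vessel_table(f), "vessel_id")
  writeLines("vessel_id,gear_class,length_m", f)
  expect_error(suppressWarnings(read_vessel_table(f)), "empty")
})

test_that("fishing records are filtered, wrapped and reject-counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,date,lat,lon,is_fishing",
               "V1,2015-03-02,10.2,-150.7,1",
               "V1,2015-03-02,10.2,-150.7,0",   # not fishing: dropped
               "V1,2015-03-03,10.2,180.0,1",    # wraps west
               "V1,bad-date,10.2,-150.7,1",     # rejected
               "V1,2015-03-04,95.0,-150.7,1"),  # rejected
             f)
  rec <- read_fishing_records(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_rejected"), 2L)
  expect_equal(rec[date == as.IDate("2015-03-03"), lon], -180)
  g <- grid_spec(1)
  expect_equal(lonlat_to_cell(g, rec$lon[2], rec$lat[2]),
               lonlat_to_cell(g, -180, 10.2))
})

test_that("a majority of rejects is a hard error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("vessel_id,date,lat,lon,is_fishing",
               "V1,bad,0,0,1", "V1,bad,0,0,1", "V1,2015-01-01,0,0,1"), f)
  expect_error(read_fishing_records(f), "50%")
})

test_that("the continuity filter keeps only vessels active in every year", {
  rec <- data.table(
    vessel_id = c("A", "A", "A", "B", "B", "C"),
    date = as.IDate(c("2015-06-01", "2016-06-01", "2017-06-01",
                      "2015-06-01", "2017-06-01", "2016-06-01")),
    lat = 0, lon = 0)
  out <- filter_continuous_vessels(rec, 2015:2017)
  expect_equal(unique(out$vessel_id), "A")
  expect_equal(attr(out, "continuity"), list(kept = 1L, dropped = 2L))
  expect_warning(filter_continuous_vessels(rec[vessel_id == "B"], 2015:2017),
                 "no vessels")
})

test_that("purse seiners split on the 40 m / 50 nm rule", {
  vt <- data.table(vessel_id = c("P1", "P2", "P3", "P4", "T1"),
                   gear_class = c(rep("purse_seines", 4), "trawlers"),
                   length_m = c(45, 30, 45, NA, 35),
                   mean_shore_distance_nm = c(60, 60, 20, 60, NA))
  expect_warning(out <- split_purse_seiners(vt), "missing length")
  expect_equal(out$fleet,
               c("purse_high_seas",  # 45 m, 60 nm: both criteria
                 "purse_coastal",    # 30 m: length fails
                 "purse_coastal",    # 20 nm: distance fails
                 "purse_coastal",    # missing length: conservative
                 "trawlers"))
})

test_that("missing shore distances are derived from positions and a raster", {
  # flat raster: 100 km everywhere -> 100/1.852 = 54 nm > 50
  r <- distance_raster(seq(-2, 2, 0.5), seq(-2, 2, 0.5),
                       matrix(100, 9, 9))
  vt <- data.table(vessel_id = "P1", gear_class = "purse_seines",
                   length_m = 45, mean_shore_distance_nm = NA_real_)
  rec <- data.table(vessel_id = "P1",
                    date = as.IDate("2015-01-01") + 0:3,
                    lat = c(0, 1, -1, 0.5), lon = c(0, 0.5, -0.5, 1))
  out <- split_purse_seiners(vt, rec, r)
  expect_equal(out$mean_shore_distance_nm, 100 / 1.852, tolerance = 1e-12)
  expect_equal(out$fleet, "purse_high_seas")
})

test_that("rasterization counts one vessel-day per vessel, cell and date", {
  g <- grid_spec(1)
  vt <- simple_vessels(c("V1", "V2"))
  rec <- data.table(
    vessel_id = c(rep("V1", 5), "V2", "V1", "V1"),
    date = as.IDate(c(rep("2015-01-10", 6), "2015-01-11", "2015-01-11")),
    lat = c(rep(0.2, 5), 0.7, 0.2, 0.2),
    lon = c(rep(0.3, 5), 0.3, 0.3, 1.3))  # last row: second cell same day
  daily <- rasterize_daily(rec, vt, g)
  d10 <- daily[date == as.IDate("2015-01-10")]
  expect_equal(sum(d10$n), 2L)  # V1 deduped to 1, plus V2
  d11 <- daily[date == as.IDate("2015-01-11")]
  expect_equal(nrow(d11), 2L)   # V1 in two distinct cells
  expect_equal(d11$n, c(1L, 1L))
})

test_that("rasterization matches a brute-force vessel-cell-day oracle and is idempotent", {
  g <- grid_spec(0.5)
  rec <- random_records(400, n_vessels = 6, seed = 7)
  vt <- simple_vessels(sprintf("V%02d", 1:6))
  daily <- rasterize_daily(rec, vt, g)
  oracle <- length(unique(paste(rec$vessel_id, rec$date,
                                lonlat_to_cell(g, rec$lon, rec$lat))))
  expect_equal(sum(daily$n), oracle)
  expect_identical(daily, rasterize_daily(rec, vt, g))
})

test_that("monthly aggregation divides by true month lengths", {
  g <- grid_spec(1)
  cellid <- lonlat_to_cell(g, 0.5, 0.5)
  daily <- data.table(gear = "trawlers",
                      date = c(seq(as.IDate("2015-01-01"),
                                   as.IDate("2015-01-31"), 1),
                               seq(as.IDate("2016-02-01"),
                                   as.IDate("2016-02-29"), 1)),
                      cell = cellid, n = 2L)
  # 62 vessel-days over January, 58 over leap February
  meg <- monthly_aggregate(daily, g,
                           coverage = c(as.IDate("2015-01-01"),
                                        as.IDate("2016-02-29")))
  expect_equal(meg$data[year == 2015 & month == 1, effort], 62 / 31)
  expect_equal(meg$data[year == 2016 & month == 2, effort], 58 / 29)
  expect_equal(total_vessel_days(meg), 62 + 58)
})

test_that("partial trailing months are excluded with a warning", {
  g <- grid_spec(1)
  daily <- data.table(gear = "trawlers",
                      date = seq(as.IDate("2015-01-01"),
                                 as.IDate("2015-02-10"), 1),
                      cell = 1L, n = 1L)
  expect_warning(meg <- monthly_aggregate(daily, g), "partial")
  expect_equal(nrow(meg$months), 1L)
  expect_equal(total_vessel_days(meg), 31)
})

test_that("vessel-day conservation holds from records to monthly grid", {
  g <- grid_spec(1)
  rec <- random_records(600, n_vessels = 8, seed = 3,
                        dates = seq(as.IDate("2015-01-01"),
                                    as.IDate("2015-04-30"), 1))
  vt <- simple_vessels(sprintf("V%02d", 1:8))
  daily <- rasterize_daily(rec, vt, g)
  meg <- monthly_aggregate(daily, g)
  expect_equal(total_vessel_days(meg), sum(daily$n))
})

test_that("finer grids retain at least as many vessel-days as coarser ones", {
  rec <- random_records(800, n_vessels = 4, seed = 9)
  vt <- simple_vessels(sprintf("V%02d", 1:4))
  vd <- sapply(c(0.5, 1, 4), function(res)
    sum(rasterize_daily(rec, vt, grid_spec(res))$n))
  expect_true(vd[1] >= vd[2] && vd[2] >= vd[3])
})

test_that("masking partitions effort exactly", {
  meg <- make_meg(matrix(runif(5 * 12, 0, 3), 5, 12), cells = c(1L, 2L, 10L, 11L, 20L))
  mask <- cell_mask(meg$grid, c(1L, 11L), label = "test")
  removed <- apply_mask(meg, mask, "remove")
  kept <- apply_mask(meg, mask, "keep")
  recombined <- rbind(removed$data, kept$data)[, .(effort = sum(effort)),
                                               by = .(gear, year, month, cell)]
  orig <- meg$data[, .(gear, year, month, cell, effort)]
  setkey(recombined, gear, year, month, cell); setkey(orig, gear, year, month, cell)
  expect_equal(recombined, orig)
  expect_equal(removed$mask_info$masked_vessel_days +
                 removed$mask_info$unmasked_vessel_days,
               total_vessel_days(meg))
  wrong <- cell_mask(grid_spec(4), 1L)
  expect_error(apply_mask(meg, wrong, "remove"), "does not match")
})

test_that("monthly grids round-trip through long-format CSV", {
  meg <- make_meg(matrix(runif(3 * 12), 3, 12), cells = c(5L, 6L, 400L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_monthly_csv(meg, f)
  back <- read_monthly_csv(f, 1)
  a <- meg$data[order(gear, year, month, cell)]
  b <- back$data[order(gear, year, month, cell)]
  expect_equal(b$effort, a$effort, tolerance = 1e-12)
  expect_equal(b$cell, a$cell)
})
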