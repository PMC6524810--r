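# independent direct evaluation of the evenness statistic, used as the
# oracle for the package's implementations
si_oracle <- function(e) {
  a <- sum(e)
  total <- 0
  for (n in 1:12) total <- total + abs(e[n] - a / 12)
  total / a
}

test_that("the climatology averages calendar months across years", {
  # Januaries 1, 2, 3 across 2015-2017 average to 2
  prof <- rbind(c(rep(1, 12), rep(2, 12), rep(3, 12)))
  clim <- climatology(make_meg(prof, years = 2015:2017))
  expect_true(all(clim$data$e_n == 2))
  expect_equal(climatology_annual(clim)$annual, 24)
  # identical years reproduce any single year
  p1 <- runif(12, 0, 4)
  clim2 <- climatology(make_meg(rbind(rep(p1, 3)), years = 2015:2017))
  expect_equal(clim2$data[order(month), e_n], p1, tolerance = 1e-12)
  # partial years are refused
  expect_error(climatology(
    monthly_effort_grid(data.table(gear = "trawlers", year = 2015,
                                   month = 1:6, cell = 1L, effort = 1),
                        grid_spec(1))), "whole")
})

test_that("the seasonality index attains its analytic extremes", {
  expect_equal(si_profile(rep(5, 12)), 0)
  expect_equal(si_profile(c(60, rep(0, 11))), 22 / 12, tolerance = 1e-15)
  expect_equal(si_profile(c(30, 30, rep(0, 10))), 20 / 12, tolerance = 1e-15)
  expect_true(is.na(si_profile(rep(0, 12))))
})

test_that("the k-active-month ladder matches the closed form and the oracle", {
  for (k in 1:12) {
    e <- c(rep(7, k), rep(0, 12 - k))
    expect_equal(si_profile(e), 2 * (12 - k) / 12, tolerance = 1e-12)
    expect_equal(si_profile(e), si_oracle(e), tolerance = 1e-15)
  }
  # the ladder is strictly decreasing in the number of active months
  ladder <- sapply(1:12, function(k) si_profile(c(rep(1, k), rep(0, 12 - k))))
  expect_true(all(diff(ladder) < 0))
})

test_that("SI is bounded, scale invariant and agrees with the oracle on random cells", {
  set.seed(17)
  for (i in 1:200) {
    e <- rexp(12) * rbinom(12, 1, 0.7)
    if (sum(e) == 0) e[1] <- 1
    s <- si_profile(e)
    expect_equal(s, si_oracle(e), tolerance = 1e-12)
    expect_gte(s, 0); expect_lte(s, 22 / 12 + 1e-12)
    expect_equal(si_profile(e * runif(1, 0.01, 100)), s, tolerance = 1e-9)
  }
  # equality cases: 0 iff uniform, 22/12 iff a single active month
  expect_lt(abs(si_profile(rep(2, 12))), 1e-15)
  e1 <- rep(1, 12); e1[4] <- 1 + 1e-6
  expect_gt(si_profile(e1), 0)
  expect_lt(si_profile(c(10, 1e-6, rep(0, 10))), 22 / 12)
})

test_that("the SI map handles sparse cells and matches per-profile evaluation", {
  profs <- rbind(rep(2, 12),
                 c(24, rep(0, 11)),
                 c(0, 0, 5, 5, rep(0, 8)))
  meg <- make_meg(profs, cells = c(1L, 2L, 3L))
  si <- seasonality_index(climatology(meg))
  got <- si$data[order(cell), si]
  expect_equal(got, c(0, 22 / 12, apply(profs, 1, si_profile)[3]),
               tolerance = 1e-12)
  # a zero-effort cell is simply absent (flagged invalid by omission)
  meg0 <- make_meg(rbind(rep(0, 12), rep(1, 12)), cells = c(9L, 10L))
  si0 <- seasonality_index(climatology(meg0))
  expect_false(9L %in% si0$data$cell)
})

test_that("local relative sd matches hand computation and is scale invariant", {
  months <- data.table(year = 2015L, month = 1:3, days = c(31L, 28L, 31L))
  mk <- function(v) monthly_effort_grid(
    data.table(gear = "trawlers", year = 2015L, month = 1:3, cell = 1L,
               effort = v), grid_spec(1), months = months)
  out <- local_relative_sd(mk(c(1, 1, 4)))
  expect_equal(out$data$rel_sd, sqrt(0.75), tolerance = 1e-12)
  expect_equal(local_relative_sd(mk(10 * c(1, 1, 4)))$data$rel_sd,
               sqrt(0.75), tolerance = 1e-12)
  expect_equal(local_relative_sd(mk(c(2, 2, 2)))$data$rel_sd, 0)
})

test_that("peak detection finds a repeated single-month spike exactly", {
  prof <- rep(0, 12); prof[6] <- 9
  meg <- make_meg(rbind(prof), cells = 42L)
  pk <- peak_month(meg)
  expect_equal(pk$data$status, "ok")
  expect_equal(pk$data$peak_month, 6L)
  expect_equal(pk$data$explained_var, 1)
})

test_that("identical years always pass the variance filter", {
  set.seed(23)
  for (i in 1:20) {
    prof <- runif(12, 0, 5)
    pk <- peak_month(make_meg(rbind(prof), cells = 7L))
    expect_equal(pk$data$explained_var, 1, tolerance = 1e-9)
    expect_equal(pk$data$status, "ok")
  }
})

test_that("zero-year and degenerate cells are filtered with reasons", {
  # no effort at all in 2016
  prof36 <- c(runif(12, 1, 2), rep(0, 12), runif(12, 1, 2))
  pk <- peak_month(make_meg(rbind(prof36), cells = 3L))
  expect_equal(pk$data$status, "zero_year")
  expect_true(is.na(pk$data$peak_month))
  # constant everywhere: nothing to decompose
  pk2 <- peak_month(make_meg(rbind(rep(4, 12)), cells = 3L))
  expect_equal(pk2$data$status, "degenerate")
})

test_that("a cosine cycle with noise at 5% of amplitude is recovered in >= 95% of cells", {
  set.seed(31)
  n <- 500
  A <- 0.6
  base <- 1 + A * cos(2 * pi * ((1:12) - 3) / 12)  # peak in March
  profs <- matrix(rep(base, n * 3), n, 36, byrow = TRUE) +
    matrix(rnorm(n * 36, 0, 0.05 * A), n, 36)
  profs[profs < 0] <- 0
  pk <- peak_month(make_meg(profs, cells = seq_len(n)))
  ok <- pk$data[status == "ok"]
  expect_gte(nrow(ok) / n, 0.95)
  expect_gte(mean(ok$peak_month == 3L), 0.95)
})

test_that("dominant gear requires strictly more than the threshold", {
  mk2 <- function(w1, w2) {
    d <- rbind(make_meg(rbind(rep(w1, 12)), years = 2015, gear = "trawlers")$data,
               make_meg(rbind(rep(w2, 12)), years = 2015, gear = "fixed_gear")$data)
    monthly_effort_grid(d, grid_spec(1),
                        months = effortseas:::month_table(2015))
  }
  expect_equal(dominant_gear(mk2(0.8, 0.2))$gear, "trawlers")
  expect_true(is.na(dominant_gear(mk2(0.5, 0.5))$gear))
  expect_true(is.na(dominant_gear(mk2(0.75, 0.25))$gear))  # exact: not dominant
  expect_equal(dominant_gear(mk2(0.76, 0.24))$gear, "trawlers")
})
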