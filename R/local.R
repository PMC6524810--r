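# Per-cell seasonal statistics: climatology, the seasonality index of the
# 12-month profile, local relative standard deviation, PCA-based
# peak-month detection with zero-year and explained-variance filters, and
# the dominant-gear map.

#' Monthly climatology of a gridded effort series
#'
#' For each gear, cell and calendar month n, the climatological effort
#' `e_n` is the mean over the years of that month's effort (absent months
#' count as zero); the annual climatological total is the sum of the 12
#' monthly values. Requires whole years.
#'
#' @param meg a [monthly_effort_grid()].
#' @return an object of class `climatology_cube`: list with `data`
#'   (`gear, cell, month, e_n`), `grid`, `n_years`, `gears`.
#' @export
climatology <- function(meg) {
  stopifnot(inherits(meg, "monthly_effort_grid"))
  per_month <- meg$months[, .N, by = month]
  if (nrow(per_month) != 12L || length(unique(per_month$N)) != 1L) {
    input_error("climatology requires whole calendar years")
  }
  n_years <- per_month$N[1]
  d <- meg$data[, .(e_n = sum(effort) / n_years), by = .(gear, cell, month)]
  structure(list(data = d[], grid = meg$grid, n_years = n_years,
                 gears = meg$gears), class = "climatology_cube")
}

#' Annual climatological effort per cell
#'
#' @param clim a [climatology()] result.
#' @param by_gear sum per gear (default) or over all gears.
#' @return a `data.table` with `cell`, `annual` (and `gear` if `by_gear`).
#' @export
climatology_annual <- function(clim, by_gear = TRUE) {
  stopifnot(inherits(clim, "climatology_cube"))
  if (by_gear) clim$data[, .(annual = sum(e_n)), by = .(gear, cell)]
  else clim$data[, .(annual = sum(e_n)), by = cell]
}

#' Seasonality index of a 12-month effort profile
#'
#' `si_profile(e)` evaluates, for a vector of (climatological) monthly
#' efforts, the evenness statistic
#' `SI = (1/a) * sum_n |e_n - a/12|` with `a = sum_n e_n` the annual
#' total. SI is 0 for a uniform profile and 22/12 (~1.83) when all effort
#' falls in a single month; it is invariant under positive rescaling of
#' the profile, and `NA` when the annual total is zero.
#'
#' @param e numeric vector of length 12, nonnegative.
#' @return the SI value, in `[0, 22/12]`, or `NA` for an all-zero profile.
#' @export
si_profile <- function(e) {
  stopifnot(length(e) == 12L, all(e >= 0))
  a <- sum(e)
  if (a <= 0) return(NA_real_)
  sum(abs(e - a / 12)) / a
}

#' Seasonality index map
#'
#' Applies [si_profile()] to every cell of a climatology (by default on
#' the all-gear summed effort, the headline map; per gear on demand).
#' Cells with zero annual effort are flagged invalid rather than raising
#' an error.
#'
#' @param clim a [climatology()] result.
#' @param by_gear compute per gear instead of on the all-gear sum.
#' @return class `seasonality_map`: list with `data`
#'   (`[gear,] cell, si, annual`) and `grid`.
#' @export
seasonality_index <- function(clim, by_gear = FALSE) {
  stopifnot(inherits(clim, "climatology_cube"))
  d <- if (by_gear) {
    clim$data[e_n > 0, si_cell(e_n, month), by = .(gear, cell)]
  } else {
    clim$data[, .(e_n = sum(e_n)), by = .(cell, month)][e_n > 0, si_cell(e_n, month), by = cell]
  }
  structure(list(data = d[], grid = clim$grid, by_gear = by_gear),
            class = "seasonality_map")
}

# SI from the sparse positive entries of a 12-month profile:
# the (12 - k) absent months each contribute |0 - a/12| = a/12.
si_cell <- function(e_n, month) {
  a <- sum(e_n)
  k <- length(e_n)
  list(si = (sum(abs(e_n - a / 12)) + (12 - k) * a / 12) / a, annual = a)
}

#' Local relative standard deviation of monthly effort
#'
#' Per gear and cell, the sample standard deviation of the monthly series
#' (all months of the window, absent months as zero) divided by the
#' window-mean monthly effort. Undefined (flagged invalid) where the mean
#' is zero; invariant under positive rescaling of a cell's series.
#'
#' @param meg a [monthly_effort_grid()] (needs >= 2 months).
#' @param by_gear compute per gear (default) or on the all-gear sum.
#' @return class `local_sd_map`: list with `data`
#'   (`[gear,] cell, mean_effort, rel_sd`) and `grid`.
#' @export
local_relative_sd <- function(meg, by_gear = TRUE) {
  stopifnot(inherits(meg, "monthly_effort_grid"))
  n <- nrow(meg$months)
  if (n < 2L) input_error("need at least 2 months")
  base <- if (by_gear) meg$data[, .(gear, cell, effort)]
          else meg$data[, .(effort = sum(effort)), by = .(cell, year, month)][, .(cell, effort)]
  by_cols <- if (by_gear) c("gear", "cell") else "cell"
  d <- base[, {
    s <- sum(effort); ss <- sum(effort^2)
    m <- s / n
    v <- max(0, (ss - n * m^2) / (n - 1))
    .(mean_effort = m, rel_sd = sqrt(v) / m)
  }, by = by_cols]
  structure(list(data = d[], grid = meg$grid, by_gear = by_gear, n_months = n),
            class = "local_sd_map")
}

#' Peak month of the seasonal cycle by principal components
#'
#' On the all-gear summed effort, each cell's year-by-month (Y x 12)
#' matrix is grand-mean centered and decomposed by SVD. A cell passes when
#' (1) its annual total is nonzero in every year, and (2) the first
#' singular mode explains at least `min_explained` of the variance
#' (sigma_1^2 / sum sigma_k^2). The climatological component is the first
#' right-singular 12-vector, sign-aligned to correlate positively with the
#' cell's mean monthly profile; the peak month is its argmax (ties to the
#' earliest month).
#'
#' @param meg a [monthly_effort_grid()] covering whole years (>= 2).
#' @param min_explained variance-fraction threshold (default 2/3).
#' @return class `peak_month_map`: list with `data`
#'   (`cell, peak_month, explained_var, status`) and `grid`. `status` is
#'   one of `"ok"`, `"zero_year"`, `"low_variance"`, `"degenerate"`;
#'   `peak_month` is `NA` unless `"ok"`.
#' @export
peak_month <- function(meg, min_explained = 2 / 3) {
  stopifnot(inherits(meg, "monthly_effort_grid"))
  per_month <- meg$months[, .N, by = month]
  if (nrow(per_month) != 12L || length(unique(per_month$N)) != 1L) {
    input_error("peak_month requires whole calendar years")
  }
  years <- sort(unique(meg$months$year))
  Y <- length(years)
  if (Y < 2L) input_error("peak_month requires at least 2 years")
  tot <- meg$data[, .(effort = sum(effort)), by = .(cell, year, month)]
  wide <- dcast(tot, cell ~ year + month, value.var = "effort", fill = 0)
  # order columns year-major, month-minor
  want <- paste(rep(years, each = 12L), rep(1:12, Y), sep = "_")
  have <- setdiff(want, names(wide))
  if (length(have)) wide[, (have) := 0]
  setcolorder(wide, c("cell", want))
  cells <- wide$cell
  M <- as.matrix(wide[, !"cell"])
  res <- data.table(cell = cells, peak_month = NA_integer_,
                    explained_var = NA_real_, status = "ok")
  for (r in seq_along(cells)) {
    X <- matrix(M[r, ], nrow = Y, byrow = TRUE)
    annual <- rowSums(X)
    if (any(annual <= 0)) {
      res[r, status := "zero_year"]
      next
    }
    C <- X - mean(X)
    totvar <- sum(C^2)
    if (totvar <= .Machine$double.eps * sum(X^2)) {
      res[r, status := "degenerate"]
      next
    }
    sv <- svd(C)
    evr <- sv$d[1]^2 / sum(sv$d^2)
    res[r, explained_var := evr]
    if (evr < min_explained) {
      res[r, status := "low_variance"]
      next
    }
    v <- sv$v[, 1]
    prof <- colMeans(X)
    if (sum(v * (prof - mean(prof))) < 0) v <- -v
    res[r, peak_month := which.max(v)]
  }
  structure(list(data = res[], grid = meg$grid, years = years,
                 min_explained = min_explained), class = "peak_month_map")
}

#' Dominant gear per cell
#'
#' A gear is dominant in a cell iff it contributes strictly more than
#' `threshold` (default 75%) of the cell's window-summed vessel-days;
#' otherwise the cell is unlabelled (`NA`), including zero-effort cells
#' and exact-threshold ties.
#'
#' @param meg a [monthly_effort_grid()].
#' @param threshold dominance fraction in (0, 1); strict inequality.
#' @return a `data.table` with `cell`, `gear` (`NA` if none), `share`.
#' @export
dominant_gear <- function(meg, threshold = 0.75) {
  stopifnot(inherits(meg, "monthly_effort_grid"), threshold > 0, threshold < 1)
  d <- meg$data[meg$months, on = c("year", "month"), nomatch = NULL]
  vd <- d[, .(vd = sum(effort * days)), by = .(cell, gear)]
  vd[, total := sum(vd), by = cell]
  top <- vd[order(cell, -vd), .SD[1], by = cell]
  top[, share := vd / total]
  top[, .(cell, gear = fifelse(share > threshold, gear, NA_character_), share)]
}

#' Seasonality maps across grid resolutions
#'
#' Reruns rasterization, climatology, SI and peak-month detection at each
#' requested resolution from the same record stream, and reports the
#' Spearman rank correlation of SI between every resolution pair: cells of
#' the finer grid are block-aggregated to the coarser grid (mean SI of the
#' finer cells inside each coarse cell) and correlated with the coarse
#' map over cells valid in both.
#'
#' @param records record table (post continuity filter).
#' @param vessel_table vessel table (post purse split).
#' @param resolutions resolutions to run (default 0.5, 1.0, 4.0).
#' @param coverage optional Date range passed to [monthly_aggregate()].
#' @return list with `maps` (per resolution: `si`, `peak`),
#'   `correlations` (`res_fine, res_coarse, spearman, n_cells`).
#' @export
seasonality_by_resolution <- function(records, vessel_table,
                                      resolutions = c(0.5, 1.0, 4.0),
                                      coverage = NULL) {
  resolutions <- sort(unique(resolutions))
  maps <- list()
  for (res in resolutions) {
    grid <- grid_spec(res)
    meg <- monthly_aggregate(rasterize_daily(records, vessel_table, grid),
                             grid, coverage = coverage)
    maps[[as.character(res)]] <- list(
      si = seasonality_index(climatology(meg)),
      peak = peak_month(meg),
      grid = grid
    )
  }
  pairs <- list()
  if (length(resolutions) > 1L) {
    combs <- utils::combn(resolutions, 2)
    for (k in seq_len(ncol(combs))) {
      rf <- combs[1, k]; rc <- combs[2, k]
      fine <- maps[[as.character(rf)]]$si
      coarse <- maps[[as.character(rc)]]$si
      fc <- copy(fine$data)
      ctr <- cell_center(fine$grid, fc$cell)
      fc[, coarse_cell := lonlat_to_cell(coarse$grid, ctr$lon, ctr$lat)]
      blk <- fc[, .(si_fine = mean(si)), by = coarse_cell]
      m <- merge(blk, coarse$data[, .(coarse_cell = cell, si_coarse = si)],
                 by = "coarse_cell")
      rho <- if (nrow(m) >= 3L) cor(m$si_fine, m$si_coarse, method = "spearman")
             else NA_real_
      pairs[[k]] <- data.table(res_fine = rf, res_coarse = rc,
                               spearman = rho, n_cells = nrow(m))
    }
  }
  list(maps = maps,
       correlations = if (length(pairs)) rbindlist(pairs) else data.table())
}
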