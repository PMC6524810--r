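# Orchestration: run the full analysis (simulate -> ingest -> global ->
# local -> port) from a single configuration, writing machine-readable
# outputs and a reproducibility manifest.

#' Build a pipeline run configuration
#'
#' Either a `scenario` (everything is simulated) or paths to the input
#' files must be given. Thresholds default to the analysis constants:
#' dominant-gear fraction 0.75, explained-variance filter 2/3, bin
#' discard fraction 0.001.
#'
#' @param scenario a [synthetic_scenario()], or `NULL` to read files.
#' @param records_path,vessels_path CSV inputs (ignored with a scenario).
#' @param mask_path GeoJSON polygon or CSV cell-center mask (with a
#'   scenario the generated EEZ is used when this is `NULL`).
#' @param port_raster_path,shore_raster_path distance rasters, CSV.
#' @param resolutions grid resolutions to run (default 0.5, 1, 4).
#' @param primary_resolution resolution used for the global, holiday and
#'   distance-profile stages (default 1.0).
#' @param years analysis window (whole calendar years).
#' @param mask_mode `"remove"` or `"keep"` for the masked global series.
#' @param bin_width_km distance-profile bin width.
#' @param dominant_threshold,variance_threshold,discard_frac analysis
#'   thresholds, each in (0, 1).
#' @param out_dir output directory.
#' @param seed integer seed governing all randomness of the run.
#' @param verbose emit progress messages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, records_path = NULL,
                       vessels_path = NULL, mask_path = NULL,
                       port_raster_path = NULL, shore_raster_path = NULL,
                       resolutions = c(0.5, 1.0, 4.0),
                       primary_resolution = 1.0,
                       years = 2015:2017, mask_mode = "remove",
                       bin_width_km = 75, dominant_threshold = 0.75,
                       variance_threshold = 2 / 3, discard_frac = 0.001,
                       out_dir = "effortseas_out", seed = 1L,
                       verbose = TRUE) {
  if (length(resolutions) < 1L) input_error("at least one resolution required")
  for (r in resolutions) grid_spec(r)  # validates
  if (!primary_resolution %in% resolutions) {
    primary_resolution <- resolutions[which.min(abs(resolutions - 1))]
  }
  for (th in c(dominant_threshold, variance_threshold, discard_frac)) {
    if (!is.finite(th) || th <= 0 || th >= 1) {
      input_error("thresholds must lie in (0, 1)")
    }
  }
  if (!mask_mode %in% c("remove", "keep")) {
    input_error("mask_mode must be 'remove' or 'keep'")
  }
  if (is.null(scenario) && (is.null(records_path) || is.null(vessels_path))) {
    input_error("either a scenario or records_path + vessels_path required")
  }
  structure(list(scenario = scenario, records_path = records_path,
                 vessels_path = vessels_path, mask_path = mask_path,
                 port_raster_path = port_raster_path,
                 shore_raster_path = shore_raster_path,
                 resolutions = sort(resolutions),
                 primary_resolution = primary_resolution,
                 years = as.integer(years), mask_mode = mask_mode,
                 bin_width_km = bin_width_km,
                 dominant_threshold = dominant_threshold,
                 variance_threshold = variance_threshold,
                 discard_frac = discard_frac,
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] may be set in the YAML file; a
#' `scenario:` block is passed to [synthetic_scenario()].
#'
#' @param path YAML file path.
#' @param ... overrides applied after the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sargs <- y$scenario
    if (!is.null(sargs$gear_shares)) sargs$gear_shares <- unlist(sargs$gear_shares)
    if (!is.null(sargs$holiday_days)) sargs$holiday_days <- unlist(sargs$holiday_days)
    if (!is.null(sargs$ports)) sargs$ports <- do.call(rbind, sargs$ports)
    if (!is.null(sargs$moratorium_windows)) {
      sargs$moratorium_windows <- lapply(sargs$moratorium_windows, unlist)
    }
    y$scenario <- do.call(synthetic_scenario, sargs)
  }
  over <- list(...)
  for (nm in names(over)) y[[nm]] <- over[[nm]]
  do.call(run_config, y)
}

write_map_csv <- function(dt, grid, path) {
  out <- copy(as.data.table(dt))
  ctr <- cell_center(grid, out$cell)
  out[, `:=`(lon = ctr$lon, lat = ctr$lat)]
  setcolorder(out, c("lon", "lat"))
  out[, cell := NULL]
  fwrite(out, path)
  invisible(path)
}

#' Run the full seasonality pipeline
#'
#' Executes simulate (when configured), ingest, global, local and port
#' stages at every requested resolution, writes each stage's outputs as
#' CSV/JSON under `out_dir`, and returns a manifest (seed, input digests,
#' per-stage record counts, output digests). Identical configurations and
#' seeds produce identical outputs.
#'
#' @param config a [run_config()] or a YAML path accepted by
#'   [read_run_config()].
#' @return the manifest, invisibly; it is also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message("[effortseas] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("effortseas")),
                   seed = config$seed, resolutions = config$resolutions,
                   stages = list())

  # -- simulate ------------------------------------------------------------
  if (!is.null(config$scenario)) {
    say("simulate: generating synthetic records")
    scn <- config$scenario
    scn$seed <- config$seed
    sim <- generate_parametric(scn)
    fwrite(sim$records, out("records.csv"))
    fwrite(sim$vessels, out("vessels.csv"))
    truth <- sim$truth
    truth$fleet_of_vessel <- NULL
    truth$peak <- NULL
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    fwrite(sim$truth$peak, out("truth_peaks.csv"))
    rasters <- generate_distance_fields(scn)
    write_distance_raster(rasters$port, out("port_distance.csv"))
    write_distance_raster(rasters$shore, out("shore_distance.csv"))
    eez <- generate_eez_mask(scn, path = out("eez.geojson"))
    config$records_path <- out("records.csv")
    config$vessels_path <- out("vessels.csv")
    if (is.null(config$mask_path)) config$mask_path <- out("eez.geojson")
    if (is.null(config$port_raster_path)) config$port_raster_path <- out("port_distance.csv")
    if (is.null(config$shore_raster_path)) config$shore_raster_path <- out("shore_distance.csv")
    manifest$stages$simulate <- list(n_records = nrow(sim$records),
                                     n_vessels = nrow(sim$vessels))
  }

  # -- ingest --------------------------------------------------------------
  say("ingest: reading and filtering records")
  vessels <- read_vessel_table(config$vessels_path)
  records <- read_fishing_records(config$records_path, vessels)
  records <- filter_continuous_vessels(records, config$years)
  shore_raster <- if (!is.null(config$shore_raster_path)) {
    read_distance_raster(config$shore_raster_path)
  } else if (!is.null(config$port_raster_path)) {
    warning("no shore raster supplied; using the port raster for the purse split",
            call. = FALSE)
    read_distance_raster(config$port_raster_path)
  } else NULL
  vessels <- split_purse_seiners(vessels, records, shore_raster)
  coverage <- as.IDate(c(sprintf("%04d-01-01", min(config$years)),
                         sprintf("%04d-12-31", max(config$years))))
  megs <- list()
  for (r in config$resolutions) {
    grid <- grid_spec(r)
    daily <- rasterize_daily(records, vessels, grid)
    megs[[as.character(r)]] <- monthly_aggregate(daily, grid, coverage = coverage)
    write_monthly_csv(megs[[as.character(r)]],
                      out(sprintf("monthly_effort_%.1fdeg.csv", r)))
  }
  manifest$stages$ingest <- list(
    n_records = nrow(records),
    continuity = attr(records, "continuity"),
    vessel_days = total_vessel_days(megs[[as.character(config$primary_resolution)]]))

  # -- global --------------------------------------------------------------
  say("global: gear series, shares, holiday estimate")
  meg1 <- megs[[as.character(config$primary_resolution)]]
  grid1 <- meg1$grid
  mask <- if (!is.null(config$mask_path)) read_mask(config$mask_path, grid1) else NULL
  series_full <- global_series(meg1)
  series_masked <- if (!is.null(mask)) {
    global_series(apply_mask(meg1, mask, mode = config$mask_mode))
  } else series_full
  rel <- relative_variation(series_masked)
  shares <- gear_shares(series_full)
  holiday <- implied_holiday_days(series_masked)
  gs <- copy(series_full$data)
  rel_all <- rel$data[gs, on = c("gear", "year", "month")]
  fwrite(rel_all[, .(gear, year, month, E, relative_E = rel)],
         out("global_series.csv"))
  summary <- list(
    gear_shares_pct = as.list(shares),
    sd_relative = as.list(stats::setNames(rel$sd$sd_rel, rel$sd$gear)),
    holiday = list(baseline_vessel_days_per_day = holiday$baseline,
                   implied_days = as.list(stats::setNames(
                     holiday$estimates$implied_days,
                     paste0("month_", holiday$estimates$month)))),
    mask = if (!is.null(mask)) list(label = mask$label, n_cells = length(mask$cells),
                                    mode = config$mask_mode) else NULL)
  jsonlite::write_json(summary, out("global_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest$stages$global <- list(n_gears = length(series_full$gears))

  # -- local ---------------------------------------------------------------
  say("local: climatology, SI, peak months, dominant gear")
  for (r in config$resolutions) {
    meg <- megs[[as.character(r)]]
    clim <- climatology(meg)
    si <- seasonality_index(clim)
    lsd <- local_relative_sd(meg)
    pk <- peak_month(meg, min_explained = config$variance_threshold)
    dom <- dominant_gear(meg, threshold = config$dominant_threshold)
    write_map_csv(si$data, meg$grid, out(sprintf("si_map_%.1fdeg.csv", r)))
    write_map_csv(lsd$data, meg$grid, out(sprintf("local_sd_%.1fdeg.csv", r)))
    write_map_csv(pk$data, meg$grid, out(sprintf("peak_month_%.1fdeg.csv", r)))
    write_map_csv(dom, meg$grid, out(sprintf("dominant_gear_%.1fdeg.csv", r)))
  }
  manifest$stages$local <- list(resolutions = config$resolutions)

  # -- port ----------------------------------------------------------------
  if (!is.null(config$port_raster_path)) {
    say("port: distance interpolation and binned variability")
    praster <- read_distance_raster(config$port_raster_path)
    clim1 <- climatology(meg1)
    lsd1 <- local_relative_sd(meg1)
    dist1 <- distance_at_cells(praster, grid1)
    prof <- binned_variability(lsd1, clim1, dist1,
                               bin_width_km = config$bin_width_km,
                               discard_frac = config$discard_frac)
    fwrite(prof, out("distance_profiles.csv"))
    manifest$stages$port <- list(n_bins = nrow(prof))
  }

  # -- manifest ------------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  say("done: ", config$out_dir)
  invisible(manifest)
}
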