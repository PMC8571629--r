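#' Pipeline configuration
#'
#' Gathers the constants of the SAV prediction and validation pipeline in
#' one object: file locations, grid geometry, the optical and clarity
#' models, classification thresholds, the validation subsample, and the
#' drawdown scenario. All defaults are the printed constants of the field
#' protocol this package models.
#'
#' @param stations_csv,grid_points_csv,counts_file Input paths (optional;
#'   commands can also be fed in-memory objects). `counts_file` is a
#'   CSV/JSON file with columns/keys `tp`, `fn`, `fp`, `tn` that lets
#'   [run_evaluate()] score published counts without rasters.
#' @param output_dir Where commands write their outputs (default a
#'   temporary directory).
#' @param outlet_xy Outlet location, planar metres.
#' @param cell_size Raster cell size, m (default 16).
#' @param fill_radius Neighbour-fill radius for rasterization, cells
#'   (default 1; see [rasterize_points()]).
#' @param light_thresholds Lower edges of light classes 2 and 3
#'   (default `c(0.15, 0.25)`).
#' @param biovolume_thresholds Lower edges of biovolume classes 2 and 3
#'   (default `c(10, 25)`).
#' @param poole_atkins_k,light_fraction_mdc See [light_params()].
#' @param secchi_slope,secchi_intercept See [secchi_model()].
#' @param subsample_fraction Validation sampling fraction (default 0.2).
#' @param seed Integer seed for the subsample and the simulator.
#' @param drawdowns,suitability_depth See [drawdown_simulation()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(stations_csv = NULL, grid_points_csv = NULL,
                            counts_file = NULL, output_dir = tempfile("lakesav"),
                            outlet_xy = c(0, 0), cell_size = 16,
                            fill_radius = 1,
                            light_thresholds = c(0.15, 0.25),
                            biovolume_thresholds = c(10, 25),
                            poole_atkins_k = 1.7, light_fraction_mdc = 0.2,
                            secchi_slope = 0.073, secchi_intercept = 0.69,
                            subsample_fraction = 0.2, seed = 1L,
                            drawdowns = c(1, 2, 2.5, 3),
                            suitability_depth = 2) {
  if (diff(light_thresholds) <= 0 || diff(biovolume_thresholds) <= 0) {
    stop_config("Class thresholds must be strictly increasing.")
  }
  structure(list(
    stations_csv = stations_csv, grid_points_csv = grid_points_csv,
    counts_file = counts_file, output_dir = output_dir,
    outlet_xy = as.numeric(outlet_xy), cell_size = cell_size,
    fill_radius = fill_radius,
    light_thresholds = light_thresholds,
    biovolume_thresholds = biovolume_thresholds,
    poole_atkins_k = poole_atkins_k, light_fraction_mdc = light_fraction_mdc,
    secchi_slope = secchi_slope, secchi_intercept = secchi_intercept,
    subsample_fraction = subsample_fraction, seed = as.integer(seed),
    drawdowns = drawdowns, suitability_depth = suitability_depth
  ), class = "pipeline_config")
}

#' Read or write a pipeline configuration (YAML or JSON)
#'
#' The on-disk format is chosen by extension (`.yaml`/`.yml` or `.json`);
#' the two are equivalent.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("No such file: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, vals)
}

config_light_params <- function(config) {
  light_params(config$poole_atkins_k, config$light_fraction_mdc)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Generate a synthetic dataset on disk
#'
#' Runs the synthetic-lake generator and writes the station CSV, the
#' grid-point CSV (one sonar-style point per wet cell, with depth and
#' observed biovolume), the truth rasters, and a provenance manifest
#' (seed, parameters, package version, config hash). Outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param sim A [lake_sim_config()].
#' @param output_dir Output directory (created if needed).
#' @param n_stations,n_months Passed to [simulate_stations()].
#' @return Invisibly, a list with the in-memory `stations`, `bathy`,
#'   `observed` grids and the file paths written.
#' @export
run_simulate <- function(sim, output_dir, n_stations = 18, n_months = 4) {
  stopifnot(inherits(sim, "lake_sim_config"))
  ensure_dir(output_dir)
  bathy <- simulate_bathymetry(sim)
  stations <- simulate_stations(sim, n_stations, n_months, bathy = bathy)
  secchi <- distance_to_outlet(bathy, sim$outlet_xy) |>
    predict_secchi_surface(secchi_model(sim$secchi_slope, sim$secchi_intercept))
  observed <- simulate_observed_sav(bathy, secchi, sim)

  wet <- !is.na(bathy$depth)
  points <- tibble::tibble(x = bathy$x[wet], y = bathy$y[wet],
                           depth = bathy$depth[wet],
                           biovolume = observed$biovolume[wet])
  paths <- list(
    stations = file.path(output_dir, "stations.csv"),
    grid_points = file.path(output_dir, "grid_points.csv"),
    depth_raster = file.path(output_dir, "depth.asc"),
    biovolume_raster = file.path(output_dir, "biovolume.asc"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_stations_csv(stations, paths$stations)
  write_grid_points_csv(points, paths$grid_points)
  write_esri_ascii(bathy, "depth", paths$depth_raster)
  write_esri_ascii(observed, "biovolume", paths$biovolume_raster)
  manifest <- list(
    generator = "lakesav synthetic lake",
    package_version = as.character(utils::packageVersion("lakesav")),
    seed = sim$seed, n_stations = n_stations, n_months = n_months,
    config = unclass(sim)[!vapply(unclass(sim), is.null, logical(1))],
    config_hash = rlang::hash(unclass(sim))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(stations = stations, bathy = bathy, observed = observed,
                 secchi = secchi, paths = paths))
}

#' Zone chemistry summary and trophic report
#'
#' Outlier-screens the station table, summarises it by zone, and derives
#' the trophic assessment (Carlson indices, limiting nutrient) for each
#' zone and the whole lake. Writes `zone_summary.csv` and
#' `trophic_assessment.csv` when `output_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @param stations Optional in-memory station tibble (else read from
#'   `config$stations_csv`).
#' @param write Write output CSVs (default `TRUE`).
#' @return A list with `summary` and `trophic` tibbles.
#' @export
run_chemistry <- function(config, stations = NULL, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(stations)) {
    if (is.null(config$stations_csv)) {
      stop_domain("No station data: set `stations_csv` or pass `stations`.")
    }
    stations <- read_stations_csv(config$stations_csv)
  }
  if (nrow(stations) == 0) stop_domain("Station table is empty.")
  screened <- remove_outliers(stations)
  summary <- summarize_zones(screened)
  trophic <- assess_trophic_state(summary)
  if (isTRUE(write)) {
    ensure_dir(config$output_dir)
    readr::write_csv(summary, file.path(config$output_dir, "zone_summary.csv"), na = "")
    readr::write_csv(trophic, file.path(config$output_dir, "trophic_assessment.csv"), na = "")
  }
  list(summary = summary, trophic = trophic)
}

#' Predict the SAV distribution from bathymetry and clarity
#'
#' Rasterizes the grid points, builds the distance-to-outlet and predicted
#' Secchi surfaces, computes percent light at the bottom, classifies it,
#' and reports the vegetated-area fraction. Rasters are written as ESRI
#' ASCII grids when `write = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param grid_points Optional in-memory grid-point tibble (else read from
#'   `config$grid_points_csv`).
#' @param write Write output rasters (default `TRUE`).
#' @return A list: `bathy`, `secchi`, `light`, `classes` grids and the
#'   `area_fraction` row.
#' @export
run_predict_sav <- function(config, grid_points = NULL, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(grid_points)) {
    if (is.null(config$grid_points_csv)) {
      stop_domain("No grid points: set `grid_points_csv` or pass `grid_points`.")
    }
    grid_points <- read_grid_points_csv(config$grid_points_csv)
  }
  bathy <- rasterize_points(grid_points, cell_size = config$cell_size,
                            fill_radius = config$fill_radius)
  secchi <- distance_to_outlet(bathy, config$outlet_xy) |>
    predict_secchi_surface(secchi_model(config$secchi_slope,
                                        config$secchi_intercept))
  light <- light_at_bottom_surface(bathy, secchi, config_light_params(config))
  classes <- classify_light(light, config$light_thresholds)
  frac <- sav_area_fraction(classes)
  if (isTRUE(write)) {
    ensure_dir(config$output_dir)
    write_esri_ascii(secchi, "secchi", file.path(config$output_dir, "secchi_pred.asc"))
    write_esri_ascii(light, "light", file.path(config$output_dir, "light_bottom.asc"))
    write_esri_ascii(classes, "class", file.path(config$output_dir, "sav_class_pred.asc"))
    readr::write_csv(frac, file.path(config$output_dir, "sav_area_fraction.csv"))
  }
  list(bathy = bathy, secchi = secchi, light = light, classes = classes,
       area_fraction = frac)
}

read_counts_file <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    as.list(readr::read_csv(path, col_types = readr::cols(), progress = FALSE))
  }
  need <- c("tp", "fn", "fp", "tn")
  if (!all(need %in% names(vals))) {
    stop_domain("Counts file must provide `tp`, `fn`, `fp`, `tn`.")
  }
  new_confusion(tp = vals$tp[[1]], fn = vals$fn[[1]],
                fp = vals$fp[[1]], tn = vals$tn[[1]])
}

#' Validate predicted against observed SAV
#'
#' Binarizes the two class grids to presence/absence, draws the random
#' validation subsample, tallies the confusion matrix and computes the
#' performance metrics. Alternatively, when `config$counts_file` is set,
#' scores published counts directly (no rasters needed).
#'
#' @param config A [pipeline_config()].
#' @param observed,predicted Class grids (e.g. from [classify_biovolume()]
#'   and [run_predict_sav()]); ignored when a counts file is configured.
#' @param write Write `confusion_counts.csv` / `confusion_metrics.csv`.
#' @return A list with `counts` and `metrics`.
#' @export
run_evaluate <- function(config, observed = NULL, predicted = NULL,
                         write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$counts_file)) {
    counts <- read_counts_file(config$counts_file)
  } else {
    if (is.null(observed) || is.null(predicted)) {
      stop_domain("Provide observed and predicted class grids (or a counts file).")
    }
    obs <- binarize(observed); prd <- binarize(predicted)
    idx <- subsample_cells(obs, prd, fraction = config$subsample_fraction,
                           seed = config$seed)
    counts <- confusion_counts(obs, prd, idx)
  }
  metrics <- confusion_metrics(counts)
  if (isTRUE(write)) {
    ensure_dir(config$output_dir)
    readr::write_csv(tidy(counts),
                     file.path(config$output_dir, "confusion_counts.csv"))
    readr::write_csv(format_metrics(metrics),
                     file.path(config$output_dir, "confusion_metrics.csv"))
  }
  list(counts = counts, metrics = metrics)
}

#' Seasonal recession habitat simulation
#'
#' Runs [drawdown_simulation()] on a bathymetric grid and writes the
#' drawdown table and, per scenario, a suitability raster (1 = at least
#' `suitability_depth` of water, 0 = shallower, -1 = dried).
#'
#' @param config A [pipeline_config()].
#' @param bathy A bathymetry `lake_grid` (e.g. from [run_predict_sav()]).
#' @param write Write outputs (default `TRUE`).
#' @return The `sav_drawdown` tibble.
#' @export
run_recession <- function(config, bathy, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- drawdown_simulation(bathy, config$drawdowns, config$suitability_depth)
  if (isTRUE(write)) {
    ensure_dir(config$output_dir)
    readr::write_csv(tibble::as_tibble(res),
                     file.path(config$output_dir, "drawdown.csv"))
    for (d in config$drawdowns) {
      nd <- bathy$depth - d
      suit <- ifelse(is.na(nd), NA_real_,
                     ifelse(nd <= 0, -1, as.numeric(nd >= config$suitability_depth)))
      g <- grid_with_layer(bathy, "suitability", suit)
      write_esri_ascii(g, "suitability",
                       file.path(config$output_dir,
                                 sprintf("suitability_dd%s.asc", gsub("\\.", "_", d))))
    }
  }
  res
}
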