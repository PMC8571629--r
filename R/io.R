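#' Read and write station-sample CSV files
#'
#' Station files use the columns `station_id, x, y, zone, date, tn_ugL,
#' tp_ugL, tchl_ugL, secchi_m` (UTF-8, header required, missing values as
#' empty fields). In memory the chemistry columns are `tn`, `tp`, `tchl`,
#' `secchi`.
#'
#' @param path File path.
#' @return A station-sample tibble.
#' @export
read_stations_csv <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    station_id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double(), zone = readr::col_character(),
    date = readr::col_character(), tn_ugL = readr::col_double(),
    tp_ugL = readr::col_double(), tchl_ugL = readr::col_double(),
    secchi_m = readr::col_double(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  check_columns(df, c("station_id", "x", "y", "date",
                      "tn_ugL", "tp_ugL", "tchl_ugL", "secchi_m"), "stations")
  dplyr::rename(df, tn = "tn_ugL", tp = "tp_ugL",
                tchl = "tchl_ugL", secchi = "secchi_m")
}

#' @rdname read_stations_csv
#' @param samples Station-sample tibble with columns `station_id`, `x`,
#'   `y`, `zone`, `date`, `tn`, `tp`, `tchl`, `secchi`.
#' @export
write_stations_csv <- function(samples, path) {
  check_columns(samples, c("station_id", "x", "y", "date",
                           "tn", "tp", "tchl", "secchi"), "samples")
  out <- samples |>
    dplyr::mutate(zone = if ("zone" %in% names(samples)) .data$zone
                  else NA_character_) |>
    dplyr::select("station_id", "x", "y", "zone", "date",
                  tn_ugL = "tn", tp_ugL = "tp",
                  tchl_ugL = "tchl", secchi_m = "secchi")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and write survey grid-point CSV files
#'
#' Grid-point files use `x_m, y_m, depth_m` and optionally
#' `biovolume_pct`; in memory the columns are `x`, `y`, `depth`,
#' `biovolume`.
#'
#' @param path File path.
#' @return A grid-point tibble ready for [rasterize_points()].
#' @export
read_grid_points_csv <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("No such file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        na = c("", "NA"), progress = FALSE)
  check_columns(df, c("x_m", "y_m", "depth_m"), "grid points")
  df <- dplyr::rename(df, x = "x_m", y = "y_m", depth = "depth_m")
  if ("biovolume_pct" %in% names(df)) {
    df <- dplyr::rename(df, biovolume = "biovolume_pct")
  }
  df
}

#' @rdname read_grid_points_csv
#' @param points Tibble with `x`, `y`, `depth` and optionally `biovolume`.
#' @export
write_grid_points_csv <- function(points, path) {
  check_columns(points, c("x", "y", "depth"), "points")
  out <- dplyr::select(points, x_m = "x", y_m = "y", depth_m = "depth")
  if ("biovolume" %in% names(points)) out$biovolume_pct <- points$biovolume
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a grid layer as an ESRI ASCII raster
#'
#' Plain-text raster interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed
#' by rows of cell values from the northern edge down.
#'
#' @param grid A `lake_grid`.
#' @param layer Layer to write.
#' @param path Output path.
#' @param nodata Value standing in for missing cells (default -9999).
#' @param digits Significant digits written (default 10).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, layer, path, nodata = -9999, digits = 10) {
  m <- grid_layer_matrix(grid, layer)
  o <- grid_origin(grid)
  header <- c(
    sprintf("ncols %d", grid_nx(grid)),
    sprintf("nrows %d", grid_ny(grid)),
    sprintf("xllcorner %.10g", o[1]),
    sprintf("yllcorner %.10g", o[2]),
    sprintf("cellsize %.10g", grid_cell_size(grid)),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1, function(row) {
    row[is.na(row)] <- nodata
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster into a lake_grid
#'
#' @param path File path.
#' @param layer Name to give the value layer (default `"value"`).
#' @return A `lake_grid` with one layer; `NODATA_value` cells become `NA`.
#' @export
read_esri_ascii <- function(path, layer = "value") {
  if (!file.exists(path)) stop_domain(sprintf("No such file: %s", path))
  lines <- readLines(path)
  parse_kv <- function(i) as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][2])
  keys <- tolower(vapply(lines[1:6], function(l)
    strsplit(trimws(l), "\\s+")[[1]][1], character(1)))
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  if (!identical(unname(keys), expected)) {
    stop_domain("Malformed ESRI ASCII header.")
  }
  nx <- as.integer(parse_kv(1)); ny <- as.integer(parse_kv(2))
  x0 <- parse_kv(3); y0 <- parse_kv(4)
  cs <- parse_kv(5); nodata <- parse_kv(6)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nx * ny) {
    stop_domain("ESRI ASCII body does not match declared dimensions.")
  }
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)  # top row first
  m[m == nodata] <- NA_real_
  lake_grid_from_matrix(m[rev(seq_len(ny)), , drop = FALSE], layer = layer,
                        origin = c(x0, y0), cell_size = cs)
}
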