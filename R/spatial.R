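#' Rasterize survey grid points onto a regular grid
#'
#' Bins point records (e.g. sonar-derived depth/biovolume grid points)
#' into square cells, each cell taking the mean of the points falling in
#' it. The grid is snapped so cell edges lie on multiples of `cell_size`.
#' Cells containing no point are filled with the mean of their occupied
#' neighbours within `fill_radius` cells (Chebyshev distance); cells with
#' no occupied neighbour stay missing (land / unsurveyed).
#'
#' @param points Data frame with columns `x`, `y` (planar metres) and one
#'   or more value columns.
#' @param cell_size Cell edge, metres (default 16).
#' @param value_cols Columns to rasterize; defaults to every non-coordinate
#'   column.
#' @param fill_radius Neighbour-fill radius in cells (default 1; 0
#'   disables filling).
#' @return A [new_lake_grid()] with one layer per value column.
#' @export
rasterize_points <- function(points, cell_size = 16, value_cols = NULL,
                             fill_radius = 1) {
  check_columns(points, c("x", "y"), "points")
  if (nrow(points) == 0) stop_domain("`points` is empty.")
  if (cell_size <= 0) stop_config("`cell_size` must be positive.")
  value_cols <- value_cols %||% setdiff(names(points), c("x", "y"))
  if (length(value_cols) == 0) stop_domain("No value columns to rasterize.")

  x0 <- floor(min(points$x) / cell_size) * cell_size
  y0 <- floor(min(points$y) / cell_size) * cell_size
  nx <- max(1L, ceiling((max(points$x) - x0) / cell_size))
  ny <- max(1L, ceiling((max(points$y) - y0) / cell_size))
  ix <- pmin(floor((points$x - x0) / cell_size) + 1L, nx)
  iy <- pmin(floor((points$y - y0) / cell_size) + 1L, ny)
  cell <- (iy - 1L) * nx + ix

  layers <- lapply(value_cols, function(v) {
    sums <- tapply(points[[v]], cell, mean, na.rm = TRUE)
    out <- rep(NA_real_, nx * ny)
    out[as.integer(names(sums))] <- as.numeric(sums)
    if (fill_radius > 0) out <- fill_neighbours(out, nx, ny, fill_radius)
    out
  })
  names(layers) <- value_cols

  gx <- x0 + (rep(seq_len(nx), times = ny) - 0.5) * cell_size
  gy <- y0 + (rep(seq_len(ny), each = nx) - 0.5) * cell_size
  df <- tibble::tibble(x = gx, y = gy)
  for (v in value_cols) df[[v]] <- layers[[v]]
  new_lake_grid(df, c(x0, y0), cell_size, nx, ny)
}

# mean of occupied neighbours within `radius` cells for empty cells
fill_neighbours <- function(vals, nx, ny, radius) {
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  empty <- is.na(m)
  if (!any(empty) || all(empty)) return(vals)
  acc <- matrix(0, ny, nx); cnt <- matrix(0L, ny, nx)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  for (k in seq_len(nrow(offs))) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    src_r <- seq_len(ny) - dy; src_c <- seq_len(nx) - dx
    ok_r <- src_r >= 1 & src_r <= ny; ok_c <- src_c >= 1 & src_c <= nx
    shifted <- matrix(NA_real_, ny, nx)
    shifted[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
    have <- !is.na(shifted)
    acc[have] <- acc[have] + shifted[have]
    cnt <- cnt + have
  }
  fill <- empty & cnt > 0
  m[fill] <- acc[fill] / cnt[fill]
  as.vector(t(m))
}

#' Euclidean distance-to-outlet surface
#'
#' Straight-line distance from each cell centre to the outlet, in
#' kilometres. The distance is purely geometric (it does not route around
#' land), matching a GIS Euclidean-distance surface from a single source
#' cell.
#'
#' @param grid A `lake_grid`.
#' @param outlet_xy Planar coordinates of the outlet, metres; must fall
#'   inside the grid extent.
#' @return The grid with a `distance_km` layer.
#' @export
distance_to_outlet <- function(grid, outlet_xy) {
  stopifnot(is_lake_grid(grid))
  o <- grid_origin(grid); cs <- grid_cell_size(grid)
  xmax <- o[1] + grid_nx(grid) * cs; ymax <- o[2] + grid_ny(grid) * cs
  if (outlet_xy[1] < o[1] || outlet_xy[1] > xmax ||
      outlet_xy[2] < o[2] || outlet_xy[2] > ymax) {
    stop_domain("`outlet_xy` lies outside the grid extent.")
  }
  d <- sqrt((grid$x - outlet_xy[1])^2 + (grid$y - outlet_xy[2])^2) / 1000
  grid_with_layer(grid, "distance_km", d)
}

#' Linear Secchi-depth-vs-distance model
#'
#' Clarity extrapolation model `SD (m) = intercept + slope * distance
#' (km)`, as fitted from station means against distance to the outlet.
#'
#' @param slope Metres of Secchi depth per kilometre (default 0.073).
#' @param intercept Secchi depth at the outlet, metres (default 0.69).
#' @return A `secchi_model` list.
#' @export
secchi_model <- function(slope = 0.073, intercept = 0.69) {
  structure(list(slope = slope, intercept = intercept),
            class = "secchi_model")
}

#' Predicted Secchi-depth surface
#'
#' Applies a [secchi_model()] to a distance surface, cell by cell.
#'
#' @param distance A `lake_grid` with a `distance_km` layer (from
#'   [distance_to_outlet()]).
#' @param model A [secchi_model()]; or a `sav_regressions` row can supply
#'   slope/intercept via [as_secchi_model()].
#' @return The grid with a `secchi` layer (m).
#' @export
predict_secchi_surface <- function(distance, model = secchi_model()) {
  stopifnot(is_lake_grid(distance))
  check_columns(distance, "distance_km", "distance")
  d <- distance$distance_km
  if (any(!is.na(d) & d < 0)) stop_domain("Distances must be non-negative.")
  sd_pred <- model$intercept + model$slope * d
  bad <- !is.na(sd_pred) & sd_pred <= 0
  if (any(bad)) {
    stop_domain(sprintf(
      "Model predicts non-positive Secchi depth for distances in [%.3f, %.3f] km.",
      min(d[bad]), max(d[bad])))
  }
  grid_with_layer(distance, "secchi", sd_pred)
}

#' Extract a secchi_model from a fitted regression suite
#'
#' @param fits A `sav_regressions` table from [fit_regressions()].
#' @param model Which fitted model to use (default the station-mean
#'   Secchi-vs-distance fit).
#' @return A [secchi_model()].
#' @export
as_secchi_model <- function(fits, model = "secchi_vs_distance") {
  row <- fits[fits$model == model, ]
  if (nrow(row) != 1) stop_domain(sprintf("No fitted model `%s`.", model))
  secchi_model(slope = unname(row$slopes[[1]][1]), intercept = row$intercept)
}

#' Percent-of-surface-light-at-bottom surface
#'
#' Cellwise [percent_irradiance()] of the bottom given depth and predicted
#' Secchi depth; missing (land) propagates.
#'
#' @param bathy `lake_grid` with a `depth` layer (m).
#' @param secchi_surface Aligned `lake_grid` with a `secchi` layer (m).
#' @param params A [light_params()].
#' @return The grid with a `light` layer (fraction in (0, 1]).
#' @export
light_at_bottom_surface <- function(bathy, secchi_surface,
                                    params = light_params()) {
  check_aligned(bathy, secchi_surface)
  check_columns(bathy, "depth", "bathy")
  check_columns(secchi_surface, "secchi", "secchi_surface")
  frac <- percent_irradiance(bathy$depth, secchi_surface$secchi, params)
  grid_with_layer(bathy, "light", frac)
}

classify_values <- function(values, breaks, lo, hi, what) {
  if (any(!is.na(values) & (values < lo | values > hi))) {
    stop_domain(sprintf("%s values must lie in [%g, %g].", what, lo, hi))
  }
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  out[ok] <- 1L + (values[ok] >= breaks[1]) + (values[ok] >= breaks[2])
  out
}

#' Classify a bottom-light surface into SAV suitability classes
#'
#' Class 1: under 15% of surface irradiance at the bottom, assumed bare;
#' class 2: 15% to under 25%, moderate vegetation expected; class 3: 25%
#' or more, abundant vegetation expected. Intervals are half-open, closed
#' on the left.
#'
#' @param surface A `lake_grid` with a `light` layer, or a numeric vector
#'   of fractions in \[0, 1\].
#' @param thresholds Lower edges of classes 2 and 3 (default
#'   `c(0.15, 0.25)`).
#' @return A grid with an integer `class` layer (kind
#'   `"predicted_light"`), or an integer vector.
#' @export
classify_light <- function(surface, thresholds = c(0.15, 0.25)) {
  if (is_lake_grid(surface)) {
    check_columns(surface, "light", "surface")
    cls <- classify_values(surface$light, thresholds, 0, 1, "Light")
    out <- grid_with_layer(surface, "class", cls)
    attr(out, "kind") <- "predicted_light"
    return(out)
  }
  classify_values(surface, thresholds, 0, 1, "Light")
}

#' Classify observed biovolume into SAV classes
#'
#' Class 1: biovolume under 10% (noise / insignificant); class 2: 10% to
#' under 25% (moderate); class 3: 25% or more (abundant).
#'
#' @param biovolume A `lake_grid` with a `biovolume` layer, or a numeric
#'   vector of percents in \[0, 100\].
#' @param thresholds Lower edges of classes 2 and 3 (default `c(10, 25)`).
#' @return A grid with an integer `class` layer (kind
#'   `"observed_biovolume"`), or an integer vector.
#' @export
classify_biovolume <- function(biovolume, thresholds = c(10, 25)) {
  if (is_lake_grid(biovolume)) {
    check_columns(biovolume, "biovolume", "biovolume")
    cls <- classify_values(biovolume$biovolume, thresholds, 0, 100, "Biovolume")
    out <- grid_with_layer(biovolume, "class", cls)
    attr(out, "kind") <- "observed_biovolume"
    return(out)
  }
  classify_values(biovolume, thresholds, 0, 100, "Biovolume")
}

#' Fraction of the lake bottom bearing vegetation
#'
#' Share of wet cells in classes 2-3 (presence), with the underlying cell
#' counts.
#'
#' @param classgrid A class grid from [classify_light()] or
#'   [classify_biovolume()].
#' @return One-row tibble: `fraction`, `n_presence`, `n_wet`.
#' @export
sav_area_fraction <- function(classgrid) {
  stopifnot(is_lake_grid(classgrid))
  check_columns(classgrid, "class", "classgrid")
  cls <- classgrid$class
  wet <- !is.na(cls)
  if (!any(wet)) stop_domain("Class grid has no wet cells.")
  tibble::tibble(fraction = mean(cls[wet] >= 2),
                 n_presence = sum(cls[wet] >= 2), n_wet = sum(wet))
}

#' Lake morphometry from a bathymetric grid
#'
#' Surface area (wet cells times cell area), volume (summed depth times
#' cell area) and the hypsographic curve: the fraction of the wet area
#' shallower than each depth threshold.
#'
#' @param bathy `lake_grid` with a `depth` layer.
#' @param depth_step Threshold spacing for the hypsographic curve, m.
#' @return A `lake_morphometry` list: `area_m2`, `area_ha`, `volume_m3`,
#'   `mean_depth_m`, `max_depth_m` and a `hypsography` tibble
#'   (`depth_m`, `fraction_shallower`).
#' @export
morphometry <- function(bathy, depth_step = 0.5) {
  stopifnot(is_lake_grid(bathy))
  check_columns(bathy, "depth", "bathy")
  depth <- bathy$depth[!is.na(bathy$depth)]
  if (length(depth) == 0) stop_domain("No wet cells in bathymetry.")
  cell_area <- grid_cell_size(bathy)^2
  # thresholds run one step past the maximum so the curve closes at 1
  thr <- seq(0, ceiling(max(depth) / depth_step) * depth_step + depth_step,
             by = depth_step)
  hyps <- tibble::tibble(
    depth_m = thr,
    fraction_shallower = vapply(thr, function(t) mean(depth < t), numeric(1))
  )
  structure(list(
    area_m2 = length(depth) * cell_area,
    area_ha = length(depth) * cell_area / 1e4,
    volume_m3 = sum(depth) * cell_area,
    mean_depth_m = mean(depth),
    max_depth_m = max(depth),
    hypsography = hyps
  ), class = "lake_morphometry")
}

#' @export
print.lake_morphometry <- function(x, ...) {
  cat(sprintf("Lake morphometry: %.1f ha, %.3g m^3, mean depth %.2f m, max %.2f m\n",
              x$area_ha, x$volume_m3, x$mean_depth_m, x$max_depth_m))
  invisible(x)
}

#' @export
autoplot.lake_morphometry <- function(object, ...) {
  ggplot2::ggplot(object$hypsography,
                  ggplot2::aes(x = .data$depth_m, y = .data$fraction_shallower)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Depth threshold (m)", y = "Fraction of area shallower") +
    ggplot2::theme_minimal()
}

#' Water-level recession (drawdown) habitat simulation
#'
#' Lowers the water level uniformly by each drawdown value and reports,
#' as fractions of the original wet area: cells that dry out (new depth
#' <= 0), remaining-wet cells shallower than 1 m, remaining-wet cells
#' shallower than `suitability_depth`, and cells at least
#' `suitability_depth` deep (suitable habitat for a large aquatic
#' herbivore). The three fractions `dried + lt_2m + ge_2m` partition the
#' original wet area; `fraction_lt_1m` is nested within
#' `fraction_lt_2m`.
#'
#' @param bathy `lake_grid` with a `depth` layer at high water.
#' @param drawdowns Water-level decreases in metres (default
#'   `c(1, 2, 2.5, 3)`); must be non-negative.
#' @param suitability_depth Minimum depth for suitable habitat, m
#'   (default 2).
#' @return A `sav_drawdown` tibble: one row per drawdown with
#'   `fraction_dried`, `fraction_lt_1m`, `fraction_lt_2m`,
#'   `fraction_ge_2m`.
#' @export
drawdown_simulation <- function(bathy, drawdowns = c(1, 2, 2.5, 3),
                                suitability_depth = 2) {
  stopifnot(is_lake_grid(bathy))
  check_columns(bathy, "depth", "bathy")
  if (any(drawdowns < 0)) stop_domain("Drawdowns must be non-negative.")
  depth <- bathy$depth[!is.na(bathy$depth)]
  if (length(depth) == 0) stop_domain("No wet cells in bathymetry.")
  n <- length(depth)
  res <- purrr::map(drawdowns, function(d) {
    nd <- depth - d
    tibble::tibble(
      drawdown = d,
      fraction_dried = sum(nd <= 0) / n,
      fraction_lt_1m = sum(nd > 0 & nd < 1) / n,
      fraction_lt_2m = sum(nd > 0 & nd < suitability_depth) / n,
      fraction_ge_2m = sum(nd >= suitability_depth) / n
    )
  }) |> dplyr::bind_rows()
  attr(res, "suitability_depth") <- suitability_depth
  class(res) <- c("sav_drawdown", class(res))
  res
}

#' @export
autoplot.sav_drawdown <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::starts_with("fraction"),
                              names_to = "component", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drawdown, y = .data$fraction,
                                     colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Drawdown (m)", y = "Fraction of original wet area") +
    ggplot2::theme_minimal()
}
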