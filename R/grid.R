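#' Regular raster grids as tibbles
#'
#' A `lake_grid` is a tibble with one row per raster cell, columns `x` and
#' `y` holding cell-centre coordinates in planar metres, plus one or more
#' value layers (`depth`, `biovolume`, `secchi`, `light`, `class`, ...).
#' The grid geometry (lower-left corner of the raster extent, cell size,
#' and dimensions) is carried in attributes so that layers can be
#' round-tripped to matrix form and to ESRI ASCII grid files. Rows are
#' stored row-major from the southern edge: `y` ascending, then `x`
#' ascending, so cell `(ix, iy)` (1-based, from the lower-left) is row
#' `(iy - 1) * nx + ix`.
#'
#' Land is encoded as `NA` in the `depth` layer (and propagates to derived
#' layers); wet cells are those with a non-missing value.
#'
#' @param data A data frame with columns `x`, `y` and at least one layer,
#'   in canonical row order (see above).
#' @param origin Numeric length-2: x/y of the lower-left corner of the
#'   raster extent (cell edges, not centres), in metres.
#' @param cell_size Cell edge length in metres; must be positive.
#' @param nx,ny Grid dimensions in cells.
#' @return A `lake_grid` tibble.
#' @export
new_lake_grid <- function(data, origin, cell_size, nx, ny) {
  if (cell_size <= 0) stop_config("`cell_size` must be positive.")
  if (nx < 1 || ny < 1) stop_config("Grid dimensions must be at least 1 cell.")
  if (nrow(data) != nx * ny) {
    stop_config(sprintf("Grid data has %d rows; expected nx * ny = %d.",
                        nrow(data), nx * ny))
  }
  out <- tibble::as_tibble(data)
  attr(out, "origin") <- as.numeric(origin)
  attr(out, "cell_size") <- as.numeric(cell_size)
  attr(out, "nx") <- as.integer(nx)
  attr(out, "ny") <- as.integer(ny)
  class(out) <- c("lake_grid", class(out))
  out
}

#' Build a lake_grid from a matrix layer
#'
#' @param m Matrix with `ny` rows and `nx` columns; `m[iy, ix]` is the cell
#'   in column `ix` from the west and row `iy` from the south.
#' @param layer Name for the value layer.
#' @inheritParams new_lake_grid
#' @return A `lake_grid` with one layer.
#' @export
lake_grid_from_matrix <- function(m, layer = "depth", origin = c(0, 0),
                                  cell_size = 16) {
  ny <- nrow(m); nx <- ncol(m)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  df <- tibble::tibble(
    x = origin[1] + (ix - 0.5) * cell_size,
    y = origin[2] + (iy - 0.5) * cell_size
  )
  df[[layer]] <- as.vector(t(m))
  new_lake_grid(df, origin, cell_size, nx, ny)
}

#' Extract a grid layer as a matrix
#'
#' @param grid A `lake_grid`.
#' @param layer Layer (column) name.
#' @return A `ny` x `nx` matrix, row 1 at the southern edge.
#' @export
grid_layer_matrix <- function(grid, layer) {
  stopifnot(is_lake_grid(grid))
  check_columns(grid, layer, "grid")
  matrix(grid[[layer]], nrow = grid_ny(grid), ncol = grid_nx(grid),
         byrow = TRUE)
}

#' @rdname new_lake_grid
#' @param x Object to test.
#' @export
is_lake_grid <- function(x) inherits(x, "lake_grid")

grid_nx <- function(g) attr(g, "nx")
grid_ny <- function(g) attr(g, "ny")

#' @rdname new_lake_grid
#' @param grid A `lake_grid`.
#' @export
grid_cell_size <- function(grid) attr(grid, "cell_size")

#' @rdname new_lake_grid
#' @export
grid_origin <- function(grid) attr(grid, "origin")

# geometry equality used by every cellwise binary operation
grids_aligned <- function(a, b, tol = 1e-9) {
  is_lake_grid(a) && is_lake_grid(b) &&
    grid_nx(a) == grid_nx(b) && grid_ny(a) == grid_ny(b) &&
    abs(grid_cell_size(a) - grid_cell_size(b)) < tol &&
    all(abs(grid_origin(a) - grid_origin(b)) < tol)
}

check_aligned <- function(a, b) {
  if (!grids_aligned(a, b)) {
    stop_align("Grids are not aligned (shape, origin and cell size must match).")
  }
  invisible(TRUE)
}

# carry one layer into a copy of the grid, preserving geometry
grid_with_layer <- function(grid, layer, values, keep = c("x", "y")) {
  df <- grid[intersect(keep, names(grid))]
  df[[layer]] <- values
  new_lake_grid(df, grid_origin(grid), grid_cell_size(grid),
                grid_nx(grid), grid_ny(grid))
}

#' @export
print.lake_grid <- function(x, ...) {
  cat(sprintf("<lake_grid> %d x %d cells, %g m cells, origin (%g, %g)\n",
              grid_nx(x), grid_ny(x), grid_cell_size(x),
              grid_origin(x)[1], grid_origin(x)[2]))
  NextMethod()
}

#' Plot a lake_grid layer
#'
#' Renders one layer of a raster grid with [ggplot2::geom_raster()]; land
#' (`NA`) cells are left blank.
#'
#' @param object A `lake_grid`.
#' @param layer Layer to plot; defaults to the first non-coordinate column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lake_grid <- function(object, layer = NULL, ...) {
  layer <- layer %||% setdiff(names(object), c("x", "y"))[1]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", fill = layer) +
    ggplot2::theme_minimal()
}
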