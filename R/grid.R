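#' Regular geographic grid specification
#'
#' All rasters in the package live on a regular lon/lat grid (EPSG:4326),
#' north-up, cell-center registered: `origin_lon`/`origin_lat` are the
#' coordinates of the *outer edge* of the upper-left cell, longitudes
#' increase eastward with column index and latitudes decrease with row
#' index. The operational product uses 1/24 decimal degree cells (~5 km at
#' the equator); that is the default cell size, but the grid is always
#' user-supplied.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell size in decimal degrees (default `1/24`).
#' @param origin_lon Longitude of the west edge of column 1.
#' @param origin_lat Latitude of the north edge of row 1.
#' @param crs Coordinate reference system identifier.
#'
#' @return An object of class `"grid_spec"`.
#' @examples
#' g <- grid_spec(40, 40, origin_lon = 5, origin_lat = 62)
#' grid_cell_center(g, 1, 1)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1 / 24,
                      origin_lon = 0, origin_lat = 0, crs = "EPSG:4326") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, origin_lon = origin_lon,
         origin_lat = origin_lat, crs = crs),
    class = "grid_spec"
  )
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %dx%d @ %.6g deg, origin (%.6g, %.6g), %s>",
          x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat, x$crs)
}

#' @export
print.grid_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol
}

#' Affine cell-index / coordinate transforms
#'
#' `grid_cell_center()` maps (row, col) to the lon/lat of the cell center;
#' `grid_rowcol()` maps lon/lat to the (row, col) of the containing cell
#' (half-open cell intervals `[edge, edge + size)`). The round trip is the
#' identity on cell centers. Both are vectorized.
#'
#' @param grid A [grid_spec()].
#' @param row,col Cell indices (1-based).
#' @param lon,lat Coordinates in decimal degrees.
#' @return `grid_cell_center()`: a list with `lon` and `lat`;
#'   `grid_rowcol()`: a list with `row` and `col` (NA outside the grid).
#' @export
grid_cell_center <- function(grid, row, col) {
  list(lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
       lat = grid$origin_lat - (row - 0.5) * grid$cell_size)
}

#' @rdname grid_cell_center
#' @export
grid_rowcol <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Raster field: one 2-D variable on a grid at one time
#'
#' A thin container pairing a numeric matrix (`n_rows` x `n_cols`) with its
#' [grid_spec()], a validity mask, a variable name and a time tag (usually a
#' [dekad()], sometimes a `Date`). Invalid pixels hold `NA` in `values`.
#'
#' @param values Numeric (or integer) matrix of dim `n_rows` x `n_cols`.
#' @param grid A [grid_spec()] matching `dim(values)`.
#' @param variable Variable name string.
#' @param time A [dekad()], a `Date`, or `NULL`.
#' @param valid Optional logical matrix; defaults to `!is.na(values)`.
#' @return An object of class `"raster_field"`.
#' @export
raster_field <- function(values, grid, variable = "", time = NULL,
                         valid = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(identical(dim(valid), dim(values)))
  values[!valid] <- NA
  structure(list(values = values, valid = valid, grid = grid,
                 variable = variable, time = time),
            class = "raster_field")
}

#' @export
print.raster_field <- function(x, ...) {
  tm <- if (inherits(x$time, "dekad")) format(x$time) else
    if (!is.null(x$time)) format(x$time) else "-"
  cat(sprintf("<raster_field '%s' %dx%d, %s, %d/%d valid>\n",
              x$variable, x$grid$n_rows, x$grid$n_cols, tm,
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Daily stack: one variable over many days on one grid
#'
#' Internal-ish container for daily time series (precipitation, SMI, NDSI):
#' values are stored pixel-major as an `n_pixels x n_days` matrix (pixels in
#' column-major raster order), which keeps the per-dekad reductions
#' vectorizable.
#'
#' @param values `n_pixels x n_days` numeric matrix (`NA` = invalid).
#' @param dates `Date` vector of length `n_days`, strictly increasing daily.
#' @param grid A [grid_spec()] with `n_rows * n_cols == nrow(values)`.
#' @param variable Variable name.
#' @return An object of class `"daily_stack"`.
#' @export
daily_stack <- function(values, dates, grid, variable = "") {
  dates <- as.Date(dates)
  stopifnot(nrow(values) == grid$n_rows * grid$n_cols,
            ncol(values) == length(dates))
  if (length(dates) > 1L)
    stopifnot(all(diff(as.integer(dates)) == 1L))
  structure(list(values = values, dates = dates, grid = grid,
                 variable = variable),
            class = "daily_stack")
}

#' @export
print.daily_stack <- function(x, ...) {
  cat(sprintf("<daily_stack '%s' %d px x %d days (%s .. %s)>\n",
              x$variable, nrow(x$values), ncol(x$values),
              format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

# columns of a daily_stack for a date range; errors if not fully covered.
# dates are consecutive daily, so indices are plain offsets.
stack_date_cols <- function(stack, first, last, what = "window") {
  i0 <- as.integer(first - stack$dates[1]) + 1L
  i1 <- as.integer(last - stack$dates[1]) + 1L
  if (i0 < 1L || i1 > length(stack$dates))
    stop("daily series does not cover ", what, " ",
         format(first), " .. ", format(last))
  i0:i1
}

# columns of a daily_stack covering a dekad; error if not fully covered
stack_dekad_cols <- function(stack, d) {
  stack_date_cols(stack, dekad_start(d), dekad_end(d), format(d))
}

# reshape helper: n_pixels vector -> raster matrix
px_to_matrix <- function(v, grid) matrix(v, nrow = grid$n_rows)
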