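#' Georeferenced elevation grid
#'
#' Container for a single-band elevation raster (DTM, DSM or CSM): a numeric
#' matrix of elevations in meters plus an affine geotransform. The convention
#' is north-up with the origin at the top-left *corner* of the top-left cell:
#' row 1 is the northernmost row, column 1 the westernmost column, cell width
#' is positive and cell height negative. Cells are areas (pixel-is-area); the
#' center of cell (i, j) is at
#' \code{x = xmin + (j - 1/2) * cell_x}, \code{y = ymax - (i - 1/2) * cell_y}.
#'
#' @param values numeric matrix of elevations (meters); \code{NA} marks
#'   missing cells and is serialized as \code{nodata}.
#' @param xmin x coordinate (meters) of the grid's west edge.
#' @param ymax y coordinate (meters) of the grid's north edge.
#' @param cell_x,cell_y cell size in meters (both positive; \code{cell_y}
#'   defaults to \code{cell_x} for square cells).
#' @param nodata sentinel written to file for missing cells; must not be a
#'   plausible in-range elevation.
#' @param crs free-text coordinate-system label carried through IO.
#'
#' @return An object of class \code{elevation_grid}.
#' @export
elevation_grid <- function(values, xmin, ymax, cell_x, cell_y = cell_x,
                           nodata = -9999, crs = "local-metric") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 1, ncol(values) >= 1)
  if (!is.finite(cell_x) || !is.finite(cell_y) || cell_x <= 0 || cell_y <= 0)
    stop("cell sizes must be positive and finite")
  if (is.finite(nodata) && any(is.finite(values) & values == nodata))
    stop("grid contains cells equal to the nodata sentinel")
  structure(
    list(values = values, xmin = xmin, ymax = ymax,
         cell_x = cell_x, cell_y = cell_y,
         nodata = nodata, crs = crs),
    class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elevation_grid> %d rows x %d cols, cell %.4g x %.4g m\n",
              nrow(v), ncol(v), x$cell_x, x$cell_y))
  cat(sprintf("  extent: x [%.3f, %.3f], y [%.3f, %.3f] (%s)\n",
              x$xmin, x$xmin + ncol(v) * x$cell_x,
              x$ymax - nrow(v) * x$cell_y, x$ymax, x$crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  elevation: [%.3f, %.3f] m, %d NA cells\n",
                min(fin), max(fin), sum(!is.finite(v))))
  invisible(x)
}

#' @export
dim.elevation_grid <- function(x) dim(x$values)

#' Cell-center coordinates
#'
#' @param grid an \code{elevation_grid}.
#' @return \code{grid_x_centers}/\code{grid_y_centers}: numeric vectors of the
#'   x (west to east) and y (north to south) coordinates of cell centers.
#' @export
grid_x_centers <- function(grid) {
  grid$xmin + (seq_len(ncol(grid$values)) - 0.5) * grid$cell_x
}

#' @rdname grid_x_centers
#' @export
grid_y_centers <- function(grid) {
  grid$ymax - (seq_len(nrow(grid$values)) - 0.5) * grid$cell_y
}

#' @return \code{grid_extent}: named vector (xmin, xmax, ymin, ymax).
#' @rdname grid_x_centers
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xmin,
    xmax = grid$xmin + ncol(grid$values) * grid$cell_x,
    ymin = grid$ymax - nrow(grid$values) * grid$cell_y,
    ymax = grid$ymax)
}

#' Map point coordinates to cell indices
#'
#' Half-open cell ownership: a point on a shared cell edge belongs to the cell
#' to its lower-right (larger column / larger row). Points outside the grid
#' extent return \code{NA}.
#'
#' @param grid an \code{elevation_grid}.
#' @param x,y point coordinates (meters), recycled to common length.
#' @return data.frame with integer columns \code{row}, \code{col}.
#' @export
grid_cell_at <- function(grid, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  col <- floor((x - grid$xmin) / grid$cell_x) + 1L
  row <- floor((grid$ymax - y) / grid$cell_y) + 1L
  # edge rule: a point exactly on the north/west edge of a cell belongs to it;
  # on the east/south boundary of the full grid it is outside
  bad <- col < 1L | col > ncol(grid$values) | row < 1L | row > nrow(grid$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Do two grids share an identical georeferenced lattice?
#' @param a,b elevation grids.
#' @param tol coordinate tolerance in meters.
#' @return logical.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cell_x - b$cell_x) < tol && abs(a$cell_y - b$cell_y) < tol
}
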