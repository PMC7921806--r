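# Plain-matrix polygon utilities. Polygons are n x 2 numeric matrices of
# vertices (columns x, y), implicitly closed. Only simple polygons are
# supported; that covers plot rectangles and buffered ROIs.

#' Axis-aligned rectangle polygon
#' @param xmin,ymin,xmax,ymax corners (meters).
#' @return 4 x 2 vertex matrix, counter-clockwise.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorized over points. Points exactly on an edge are resolved by the
#' half-open crossing rule (an edge counts when it spans the point's y as
#' [ymin, ymax)), which is consistent but boundary points should be avoided
#' by callers that need a strict interior test.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Polygon area (shoelace formula)
#' @param poly n x 2 vertex matrix.
#' @return area in square meters (absolute value).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Polygon bounding box
#' @param poly n x 2 vertex matrix.
#' @return named vector (xmin, xmax, ymin, ymax).
#' @export
polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

#' Inward buffer of a convex polygon
#'
#' Offsets every edge inward by \code{buffer_m} and re-intersects the
#' supporting half-planes. Vertices must be in counter-clockwise order.
#' For rectangles this is the usual shrink by \code{buffer_m} on each side.
#'
#' @param poly convex n x 2 vertex matrix, counter-clockwise.
#' @param buffer_m non-negative inward offset (meters).
#' @return vertex matrix of the shrunken polygon, or NULL when the polygon
#'   collapses to nothing.
#' @export
buffer_inward <- function(poly, buffer_m) {
  stopifnot(buffer_m >= 0)
  if (buffer_m == 0) return(poly)
  n <- nrow(poly)
  # inward-offset supporting lines: edge i from v[i] to v[i+1]
  a <- numeric(n); b <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1 else i + 1, ]
    d <- q - p; len <- sqrt(sum(d^2))
    nrm <- c(-d[2], d[1]) / len       # inward normal for CCW order
    a[i] <- nrm[1]; b[i] <- nrm[2]
    cc[i] <- sum(nrm * p) + buffer_m  # half-plane a x + b y >= cc
  }
  verts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    det <- a[i] * b[j] - a[j] * b[i]
    if (abs(det) < 1e-12) return(NULL)
    verts[i, ] <- c(cc[i] * b[j] - cc[j] * b[i], a[i] * cc[j] - a[j] * cc[i]) / det
  }
  # collapsed if any offset vertex violates another half-plane
  for (i in seq_len(n))
    if (any(a * verts[i, 1] + b * verts[i, 2] < cc - 1e-9)) return(NULL)
  verts
}
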