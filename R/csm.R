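#' Crop surface model: DSM minus DTM
#'
#' Computes the per-cell canopy height above ground by subtracting a digital
#' terrain model (bare soil) from a digital surface model (top of canopy),
#' on the DSM's grid. Cells that are missing in either input are missing in
#' the output.
#'
#' @param dsm,dtm \code{\link{elevation_grid}} objects. Under
#'   \code{alignment = "exact"} they must share an identical lattice;
#'   \code{"snap"} resamples the DTM onto the DSM grid by nearest neighbor,
#'   \code{"bilinear"} by bilinear interpolation.
#' @param alignment one of \code{"exact"}, \code{"snap"}, \code{"bilinear"}.
#' @param clamp_negative if \code{TRUE}, negative heights (DTM above DSM,
#'   usually terrain-model error) are set to 0. Off by default so they stay
#'   visible as a diagnostic.
#' @return an \code{elevation_grid} of canopy heights (meters).
#' @export
compute_csm <- function(dsm, dtm, alignment = c("exact", "snap", "bilinear"),
                        clamp_negative = FALSE) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(dsm, "elevation_grid"), inherits(dtm, "elevation_grid"))
  ea <- grid_extent(dsm); eb <- grid_extent(dtm)
  if (ea["xmin"] >= eb["xmax"] || eb["xmin"] >= ea["xmax"] ||
      ea["ymin"] >= eb["ymax"] || eb["ymin"] >= ea["ymax"])
    stop("DSM and DTM do not overlap spatially")
  if (alignment == "exact") {
    if (!grids_aligned(dsm, dtm))
      stop("grids are not identical; use alignment = \"snap\" or \"bilinear\" to resample")
    ground <- dtm$values
  } else {
    ground <- resample_onto(dtm, dsm,
                            method = if (alignment == "snap") "nearest" else "bilinear")$values
  }
  out <- dsm$values - ground
  if (clamp_negative) out[!is.na(out) & out < 0] <- 0
  elevation_grid(out, xmin = dsm$xmin, ymax = dsm$ymax,
                 cell_x = dsm$cell_x, cell_y = dsm$cell_y,
                 nodata = dsm$nodata, crs = dsm$crs)
}

#' Resample one grid onto another grid's lattice
#'
#' @param src grid supplying values.
#' @param template grid supplying the target lattice.
#' @param method \code{"nearest"} or \code{"bilinear"}. Bilinear treats cell
#'   centers as sample points; target centers outside the hull of source
#'   centers fall back to nearest neighbor; missing neighbors propagate NA.
#' @return an \code{elevation_grid} on the template lattice.
#' @export
resample_onto <- function(src, template, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  xs <- grid_x_centers(template); ys <- grid_y_centers(template)
  nr <- length(ys); nc <- length(xs)
  # fractional source index of each target center (1-based, at centers)
  fx <- (rep(xs, each = nr) - src$xmin) / src$cell_x + 0.5
  fy <- (src$ymax - rep(ys, times = nc)) / src$cell_y + 0.5
  snr <- nrow(src$values); snc <- ncol(src$values)
  if (method == "nearest") {
    j <- pmin(pmax(round(fx), 1), snc)
    i <- pmin(pmax(round(fy), 1), snr)
    outside <- fx < 0.5 | fx > snc + 0.5 | fy < 0.5 | fy > snr + 0.5
    vals <- src$values[cbind(i, j)]
    vals[outside] <- NA_real_
  } else {
    j0 <- pmin(pmax(floor(fx), 1), snc - 1); i0 <- pmin(pmax(floor(fy), 1), snr - 1)
    wx <- pmin(pmax(fx - j0, 0), 1); wy <- pmin(pmax(fy - i0, 0), 1)
    v00 <- src$values[cbind(i0, j0)];     v01 <- src$values[cbind(i0, j0 + 1)]
    v10 <- src$values[cbind(i0 + 1, j0)]; v11 <- src$values[cbind(i0 + 1, j0 + 1)]
    vals <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
            wy * ((1 - wx) * v10 + wx * v11)
    outside <- fx < 0.5 | fx > snc + 0.5 | fy < 0.5 | fy > snr + 0.5
    vals[outside] <- NA_real_
  }
  elevation_grid(matrix(vals, nr, nc), xmin = template$xmin, ymax = template$ymax,
                 cell_x = template$cell_x, cell_y = template$cell_y,
                 nodata = template$nodata, crs = template$crs)
}

#' Sample a ground target's height from a CSM
#'
#' Robust height estimate at a surveyed target: the median of CSM cells whose
#' centers fall inside a square footprint centered on the target's surveyed
#' position. The median resists cells straddling the pillar edge.
#'
#' @param csm an \code{elevation_grid} of canopy/target heights (meters).
#' @param x,y target center coordinates (meters).
#' @param footprint_m side length of the square footprint (meters).
#' @return list with \code{height_m} (NA when every cell in the footprint is
#'   missing), \code{n_cells}, and \code{flag} ("ok", "all_nodata" or
#'   "outside_extent").
#' @export
sample_target_height <- function(csm, x, y, footprint_m = 0.3) {
  ext <- grid_extent(csm)
  if (x < ext["xmin"] || x > ext["xmax"] || y < ext["ymin"] || y > ext["ymax"])
    return(list(height_m = NA_real_, n_cells = 0L, flag = "outside_extent"))
  half <- footprint_m / 2
  xs <- grid_x_centers(csm); ys <- grid_y_centers(csm)
  jj <- which(xs >= x - half & xs < x + half)
  ii <- which(ys > y - half & ys <= y + half)
  vals <- as.vector(csm$values[ii, jj, drop = FALSE])
  n <- sum(!is.na(vals))
  if (n == 0) return(list(height_m = NA_real_, n_cells = 0L, flag = "all_nodata"))
  list(height_m = stats::median(vals, na.rm = TRUE), n_cells = n, flag = "ok")
}
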