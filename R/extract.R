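#' Build buffered plot regions of interest
#'
#' Shrinks every plot polygon inward by \code{buffer_m} so extracted pixels
#' come only from the plot's own canopy (a guard against shading and canopy
#' overlap from neighboring plots). The default 0.1 m matches common practice
#' for two-bed breeding plots.
#'
#' @param layout a \code{\link{field_layout}}.
#' @param buffer_m non-negative inward buffer (meters).
#' @return list of \code{plot_roi} objects: plot_id, polygon (buffered),
#'   source_polygon, buffer_m.
#' @export
build_rois <- function(layout, buffer_m = 0.1) {
  stopifnot(buffer_m >= 0)
  bad <- character(0)
  rois <- lapply(seq_len(nrow(layout$plots)), function(i) {
    id <- layout$plots$plot_id[i]
    src <- layout$polygons[[id]]
    inner <- buffer_inward(src, buffer_m)
    if (is.null(inner)) { bad <<- c(bad, id); return(NULL) }
    structure(list(plot_id = id, polygon = inner, source_polygon = src,
                   buffer_m = buffer_m), class = "plot_roi")
  })
  if (length(bad))
    stop("buffer of ", buffer_m, " m collapses plots to empty polygons: ",
         paste(bad, collapse = ", "))
  names(rois) <- layout$plots$plot_id
  rois
}

#' Extract CSM pixels falling inside an ROI
#'
#' Takes every non-missing CSM cell whose *center* lies inside the ROI
#' polygon (the package-wide center-in-polygon rule; no partial-coverage
#' weighting). Restricted to the polygon's bounding box before the
#' point-in-polygon test, which is exact, so the result equals a brute-force
#' test over every cell center.
#'
#' @param csm crop-surface \code{\link{elevation_grid}} (meters).
#' @param roi a \code{plot_roi} from \code{\link{build_rois}}, or a bare
#'   vertex matrix.
#' @return list of class \code{pixel_sample}: plot_id, values (meters),
#'   n_pixels.
#' @export
extract_pixels <- function(csm, roi) {
  poly <- if (inherits(roi, "plot_roi")) roi$polygon else roi
  id <- if (inherits(roi, "plot_roi")) roi$plot_id else NA_character_
  bb <- polygon_bbox(poly)
  xs <- grid_x_centers(csm); ys <- grid_y_centers(csm)
  jj <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
  ii <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
  if (!length(jj) || !length(ii))
    return(structure(list(plot_id = id, values = numeric(0), n_pixels = 0L),
                     class = "pixel_sample"))
  px <- rep(xs[jj], each = length(ii))
  py <- rep(ys[ii], times = length(jj))
  keep <- points_in_polygon(px, py, poly)
  vals <- as.vector(csm$values[ii, jj, drop = FALSE])[keep]
  vals <- vals[!is.na(vals)]
  structure(list(plot_id = id, values = vals, n_pixels = length(vals)),
            class = "pixel_sample")
}

#' Reduce a pixel sample to one plant-height value
#'
#' The default statistic, \code{mean_above_p75}, thresholds the sample at its
#' 75th percentile (linear interpolation between order statistics, the usual
#' quantile definition in scientific software) and averages the values
#' strictly above it; when no value is strictly above the threshold (ties at
#' the top, e.g. a constant sample) it averages the values equal to or above
#' the threshold instead, so a constant sample returns the constant.
#' Restricting to the top quartile tracks the canopy top: the plain mean is
#' diluted by leaves and gaps below the spikes, while very high percentiles
#' alone can be too selective.
#'
#' @param sample a \code{pixel_sample} (values in meters).
#' @param statistic one of "mean_above_p75", "mean", "median", "p90", "p95",
#'   "p99".
#' @param min_pixels minimum sample size; below it the value is missing with
#'   a reason flag.
#' @return list: value_cm, n_pixels, flag ("ok"/"too_few_pixels"), statistic.
#' @export
plot_height <- function(sample, statistic = "mean_above_p75", min_pixels = 30L) {
  statistic <- match.arg(statistic,
                         c("mean_above_p75", "mean", "median", "p90", "p95", "p99"))
  v <- sample$values
  if (length(v) < min_pixels)
    return(list(value_cm = NA_real_, n_pixels = length(v),
                flag = "too_few_pixels", statistic = statistic))
  val_m <- switch(statistic,
    mean_above_p75 = {
      q <- stats::quantile(v, 0.75, type = 7, names = FALSE)
      upper <- v[v > q]
      if (length(upper)) mean(upper) else mean(v[v >= q])
    },
    mean = mean(v),
    median = stats::median(v),
    p90 = stats::quantile(v, 0.90, type = 7, names = FALSE),
    p95 = stats::quantile(v, 0.95, type = 7, names = FALSE),
    p99 = stats::quantile(v, 0.99, type = 7, names = FALSE))
  list(value_cm = 100 * val_m, n_pixels = length(v), flag = "ok",
       statistic = statistic)
}

#' Extract a whole trial's aerial heights
#'
#' Batch driver: one row per plot x stage, ordered by plot_id within stage.
#' Per-plot failures (too few pixels, empty ROIs) are reported in the flag
#' column, never dropped.
#'
#' @param csm_by_stage named list of CSM grids, one per growth stage.
#' @param rois list from \code{\link{build_rois}}.
#' @param layout the \code{\link{field_layout}} supplying design attributes.
#' @param statistic,min_pixels passed to \code{\link{plot_height}}.
#' @return data.frame: plot_id, genotype, rep, block, stage, platform
#'   ("aerial"), ph_cm, n_pixels, flag.
#' @export
extract_trial <- function(csm_by_stage, rois, layout,
                          statistic = "mean_above_p75", min_pixels = 30L) {
  stopifnot(is.list(csm_by_stage), !is.null(names(csm_by_stage)))
  plots <- layout$plots[order(layout$plots$plot_id), ]
  out <- list()
  for (stage in names(csm_by_stage)) {
    csm <- csm_by_stage[[stage]]
    res <- lapply(plots$plot_id, function(id) {
      s <- extract_pixels(csm, rois[[id]])
      plot_height(s, statistic = statistic, min_pixels = min_pixels)
    })
    out[[stage]] <- data.frame(
      plot_id = plots$plot_id, genotype = plots$genotype,
      rep = plots$rep, block = plots$block, stage = stage, platform = "aerial",
      ph_cm = vapply(res, `[[`, numeric(1), "value_cm"),
      n_pixels = vapply(res, `[[`, integer(1), "n_pixels"),
      flag = vapply(res, `[[`, character(1), "flag"))
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  tbl
}
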