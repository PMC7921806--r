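# Georeferencing accuracy accounting against surveyed ground targets.
# All statistics use the population SD convention (divide by n) so the
# identity RMSE^2 = mean^2 + SD^2 holds exactly; sample SD is available
# via sd_convention = "sample".

delta_stats <- function(d, sd_convention = "population") {
  n <- length(d)
  m <- mean(d)
  ss <- mean((d - m)^2)
  sdv <- if (sd_convention == "sample" && n > 1) sqrt(ss * n / (n - 1)) else sqrt(ss)
  c(mean = m, sd = sdv, rmse = sqrt(mean(d^2)), n = n)
}

#' Horizontal georeferencing accuracy from checkpoints
#'
#' Per-axis differences delta = measured - surveyed over the checkpoint
#' targets (targets not used in bundle adjustment), with mean, SD and RMSE
#' per axis. Operates in projected meters.
#'
#' @param targets data.frame with role, surveyed_x/y, measured_x/y (meters);
#'   only rows with role "checkpoint" are used unless \code{role = NULL}.
#' @param role target role to keep ("checkpoint" default, "gcp", or NULL for
#'   all).
#' @param sd_convention "population" (default, divide by n) or "sample".
#' @return list of class \code{georef_report}: delta_x, delta_y (meters),
#'   per-axis mean/sd/rmse, n_targets.
#' @export
horizontal_deltas <- function(targets, role = "checkpoint",
                              sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  t <- if (is.null(role)) targets else targets[targets$role == role, ]
  t <- t[stats::complete.cases(t[, c("surveyed_x", "surveyed_y",
                                     "measured_x", "measured_y")]), ]
  if (nrow(t) < 1)
    stop("no ", if (is.null(role)) "targets" else role,
         " with both surveyed and measured coordinates")
  dx <- t$measured_x - t$surveyed_x
  dy <- t$measured_y - t$surveyed_y
  structure(list(delta_x = dx, delta_y = dy,
                 x = delta_stats(dx, sd_convention),
                 y = delta_stats(dy, sd_convention),
                 n_targets = nrow(t), sd_convention = sd_convention),
            class = "georef_report")
}

#' Vertical accuracy: CSM-derived vs surveyed target heights
#'
#' Samples each target's height from the CSM (median over the target
#' footprint), regresses measured on surveyed height by least squares, and
#' reports slope, intercept, R-squared, residual RMSE and the SD/RMSE of the
#' raw height errors.
#'
#' @param targets data.frame with surveyed_x/y and surveyed_z (meters).
#' @param csm crop-surface \code{\link{elevation_grid}}.
#' @param footprint_m square footprint sampled per target (meters).
#' @param sd_convention as in \code{\link{horizontal_deltas}}.
#' @return list of class \code{georef_report}: regression slope/intercept/
#'   r_squared, rmse_residual_m, error stats (mean/sd/rmse of measured -
#'   surveyed, meters), per-target table.
#' @export
vertical_accuracy <- function(targets, csm, footprint_m = 0.3,
                              sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  meas <- vapply(seq_len(nrow(targets)), function(i)
    sample_target_height(csm, targets$surveyed_x[i], targets$surveyed_y[i],
                         footprint_m)$height_m, numeric(1))
  ok <- !is.na(meas) & is.finite(targets$surveyed_z)
  z <- targets$surveyed_z[ok]; m <- meas[ok]
  if (sum(ok) < 3) stop("vertical accuracy needs at least 3 measurable targets")
  if (max(z) - min(z) <= 0)
    stop("surveyed target heights have zero range; R-squared undefined")
  fit <- stats::lm(m ~ z)
  dz <- m - z
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(
    slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    rmse_residual_m = sqrt(mean(stats::residuals(fit)^2)),
    z = delta_stats(dz, sd_convention),
    table = data.frame(target_id = targets$target_id[ok], surveyed_z = z,
                       measured_z = m, delta_z = dz),
    n_targets = sum(ok), sd_convention = sd_convention),
    class = "georef_report")
}

#' Apply GSD-multiple accuracy criteria
#'
#' Accepted practice grades orthomosaic accuracy in multiples of the ground
#' sampling distance: horizontal SD within one to two GSD per axis, vertical
#' SD within two to three GSD. The pass flags use the permissive bound (2x
#' horizontal, 3x vertical); the stricter 1x / 2x verdicts are reported
#' alongside.
#'
#' @param report a \code{georef_report} (horizontal, vertical, or a list with
#'   both under \code{$horizontal} / \code{$vertical}).
#' @param gsd_m ground sampling distance in meters.
#' @return data.frame with one row per available axis: axis, sd_m, threshold
#'   multiples, strict and permissive pass flags.
#' @export
check_accuracy_criteria <- function(report, gsd_m) {
  stopifnot(gsd_m > 0)
  rows <- list()
  grab <- function(rep) {
    if (!is.null(rep$x)) {
      rows[[length(rows) + 1]] <<- data.frame(
        axis = "x", sd_m = unname(rep$x["sd"]), limit_multiple = 2,
        pass = unname(rep$x["sd"]) <= 2 * gsd_m,
        pass_strict = unname(rep$x["sd"]) <= 1 * gsd_m)
      rows[[length(rows) + 1]] <<- data.frame(
        axis = "y", sd_m = unname(rep$y["sd"]), limit_multiple = 2,
        pass = unname(rep$y["sd"]) <= 2 * gsd_m,
        pass_strict = unname(rep$y["sd"]) <= 1 * gsd_m)
    }
    if (!is.null(rep$z))
      rows[[length(rows) + 1]] <<- data.frame(
        axis = "z", sd_m = unname(rep$z["sd"]), limit_multiple = 3,
        pass = unname(rep$z["sd"]) <= 3 * gsd_m,
        pass_strict = unname(rep$z["sd"]) <= 2 * gsd_m)
  }
  if (inherits(report, "georef_report")) grab(report)
  else { if (!is.null(report$horizontal)) grab(report$horizontal)
         if (!is.null(report$vertical)) grab(report$vertical) }
  if (!length(rows)) stop("report carries no axis SDs")
  out <- do.call(rbind, rows)
  out$gsd_m <- gsd_m
  rownames(out) <- NULL
  out
}
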