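# Ground-vs-aerial agreement: outlier screening by studentized residuals,
# per-stage regression agreement, and the cross-stage deviation RMSE.

#' Flag gross-error pairs by externally studentized residuals
#'
#' Regresses ground height on aerial height (the default direction anchors
#' studentization on the ground values; flip with \code{direction}), computes
#' externally studentized residuals, and flags pairs whose two-sided p-value
#' on n - 3 degrees of freedom survives a Bonferroni correction at
#' \code{alpha}. Flagged pairs are meant to be removed from both vectors
#' before any agreement statistic.
#'
#' @param ground,aerial paired heights (cm), n >= 5.
#' @param alpha familywise error level of the Bonferroni test.
#' @param direction "ground_on_aerial" (default) or "aerial_on_ground".
#' @return list: outliers (indices into the input pairs), studentized
#'   residuals, p_bonferroni.
#' @export
flag_outliers <- function(ground, aerial, alpha = 0.01,
                          direction = c("ground_on_aerial", "aerial_on_ground")) {
  direction <- match.arg(direction)
  stopifnot(length(ground) == length(aerial))
  ok <- stats::complete.cases(ground, aerial)
  n <- sum(ok)
  if (n < 5) stop("outlier screening needs at least 5 complete pairs")
  g <- ground[ok]; a <- aerial[ok]
  if (direction == "ground_on_aerial") {
    if (stats::sd(a) == 0) stop("aerial values are constant; regression degenerate")
    fit <- stats::lm(g ~ a)
  } else {
    if (stats::sd(g) == 0) stop("ground values are constant; regression degenerate")
    fit <- stats::lm(a ~ g)
  }
  tstud <- stats::rstudent(fit)           # external studentization, df = n - 3
  p <- 2 * stats::pt(-abs(tstud), df = n - 3)
  p_bonf <- pmin(1, p * n)
  idx_ok <- which(ok)
  list(outliers = idx_ok[which(p_bonf < alpha)],
       studentized = tstud, p_bonferroni = p_bonf, n = n)
}

#' Ground-vs-aerial agreement report
#'
#' Simple least-squares regression of aerial on ground with R-squared, slope,
#' intercept and the slope-test p-value; plus two deliberately distinct RMSEs:
#' the regression-residual RMSE (scatter around the fitted line) and the
#' raw-difference RMSE sqrt(mean((aerial - ground)^2)) which also absorbs any
#' systematic offset, together with the bias (mean aerial - ground).
#'
#' @param ground,aerial paired heights (cm), outlier screening already
#'   applied (or deliberately skipped).
#' @param outliers_removed ids or indices recorded in the report, for
#'   provenance.
#' @return list of class \code{agreement_report}: n, pearson_r, r_squared,
#'   slope, intercept, p_value, rmse_regression_cm, rmse_difference_cm,
#'   bias_cm, outliers_removed.
#' @export
agreement <- function(ground, aerial, outliers_removed = character(0)) {
  ok <- stats::complete.cases(ground, aerial)
  g <- ground[ok]; a <- aerial[ok]
  n <- length(g)
  if (n < 3) stop("agreement needs at least 3 complete pairs")
  fit <- stats::lm(a ~ g)
  # a perfect fit is legitimate here (noise-free simulations); silence lm's note
  sm <- suppressWarnings(summary(fit))
  r <- stats::cor(g, a)
  d <- a - g
  structure(list(
    n = n, pearson_r = r, r_squared = r^2,
    slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
    p_value = unname(sm$coefficients[2, 4]),
    rmse_regression_cm = sqrt(mean(stats::residuals(fit)^2)),
    rmse_difference_cm = sqrt(mean(d^2)),
    bias_cm = mean(d),
    outliers_removed = outliers_removed),
    class = "agreement_report")
}

#' Pooled deviation RMSE across growth stages
#'
#' sqrt of the mean squared aerial-minus-ground difference over every plot x
#' stage pair, with the per-stage decomposition. Invariant to stage labels
#' and record order.
#'
#' @param records data.frame with columns stage, ground_cm, aerial_cm (NA
#'   pairs dropped).
#' @return list of class \code{deviation_summary}: rmse_dev_cm, per_stage
#'   (stage, n, rmse_cm), n_total.
#' @export
rmse_dev <- function(records) {
  stopifnot(all(c("stage", "ground_cm", "aerial_cm") %in% names(records)))
  rec <- records[stats::complete.cases(records$ground_cm, records$aerial_cm), ]
  if (nrow(rec) == 0) stop("no complete ground/aerial pairs")
  d2 <- (rec$aerial_cm - rec$ground_cm)^2
  per <- aggregate(d2, by = list(stage = rec$stage),
                   FUN = function(v) c(n = length(v), mse = mean(v)))
  per_stage <- data.frame(stage = per$stage,
                          n = per$x[, "n"],
                          rmse_cm = sqrt(per$x[, "mse"]))
  structure(list(rmse_dev_cm = sqrt(mean(d2)),
                 per_stage = per_stage[order(per_stage$stage), ],
                 n_total = nrow(rec)),
            class = "deviation_summary")
}

#' Stage-wise agreement driver
#'
#' Merges ground and aerial height tables on plot and stage, screens
#' outliers per stage, and returns per-stage agreement reports plus the
#' pooled deviation RMSE (computed after outlier removal).
#'
#' @param heights long-format height table with plot_id, stage, platform
#'   ("ground"/"aerial"), ph_cm.
#' @param alpha Bonferroni level for \code{\link{flag_outliers}}; NULL skips
#'   screening.
#' @return list: per_stage (named list of agreement_report), rmse_dev
#'   (deviation_summary), merged (the paired table with outlier flags).
#' @export
agreement_by_stage <- function(heights, alpha = 0.01) {
  stopifnot(all(c("plot_id", "stage", "platform", "ph_cm") %in% names(heights)))
  g <- heights[heights$platform == "ground", c("plot_id", "stage", "ph_cm")]
  a <- heights[heights$platform == "aerial", c("plot_id", "stage", "ph_cm")]
  names(g)[3] <- "ground_cm"; names(a)[3] <- "aerial_cm"
  merged <- merge(g, a, by = c("plot_id", "stage"))
  merged$outlier <- FALSE
  reports <- list()
  for (st in sort(unique(merged$stage))) {
    rows <- which(merged$stage == st)
    gg <- merged$ground_cm[rows]; aa <- merged$aerial_cm[rows]
    removed <- character(0)
    if (!is.null(alpha) && sum(stats::complete.cases(gg, aa)) >= 5) {
      fl <- flag_outliers(gg, aa, alpha = alpha)
      if (length(fl$outliers)) {
        merged$outlier[rows[fl$outliers]] <- TRUE
        removed <- merged$plot_id[rows[fl$outliers]]
        gg <- gg[-fl$outliers]; aa <- aa[-fl$outliers]
      }
    }
    reports[[st]] <- agreement(gg, aa, outliers_removed = removed)
  }
  clean <- merged[!merged$outlier, ]
  list(per_stage = reports, rmse_dev = rmse_dev(clean), merged = merged)
}
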