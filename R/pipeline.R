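# End-to-end orchestration: simulate a trial, build CSMs, extract plot
# heights, validate georeferencing, fit the genetic models and report
# ground-vs-aerial agreement, optionally persisting every artifact with a
# hashed manifest.

#' Simulate a complete trial
#'
#' Bundles the generator stages under one seed: layout, terrain, genetic
#' truth, ground targets, per-stage canopy surfaces (DSMs) and ground
#' measurements.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param stages growth stages to realize (default: all configured).
#' @return list: config, layout, terrain, truth, targets, dsm (named list by
#'   stage), ground (data.frame).
#' @export
simulate_trial <- function(config, stages = names(config$stage_mean_cm)) {
  layout <- simulate_layout(config)
  terrain <- simulate_terrain(config)
  truth <- simulate_genotype_truth(config, layout)
  targets <- place_targets(config, layout)
  dsm <- lapply(stages, function(st)
    simulate_canopy_surface(terrain, layout, truth, config, st, targets = targets))
  names(dsm) <- stages
  ground <- do.call(rbind, lapply(stages, function(st)
    simulate_ground_measurements(layout, truth, config, st)))
  rownames(ground) <- NULL
  list(config = config, layout = layout, terrain = terrain, truth = truth,
       targets = targets, dsm = dsm, ground = ground)
}

#' Run the full phenotyping pipeline on a simulated trial
#'
#' simulate -> CSM -> buffered-ROI extraction -> georeferencing validation ->
#' genetic models -> ground-vs-aerial agreement. When \code{out_dir} is given
#' every artifact is written (GeoTIFF rasters, GeoJSON layout, CSV tables,
#' JSON reports) and a manifest with content hashes is saved, so reruns with
#' the same config and seed produce byte-identical outputs.
#'
#' @param config a \code{\link{simulation_config}} (or path to a YAML config).
#' @param out_dir output directory; NULL keeps everything in memory.
#' @param buffer_m ROI inward buffer (meters).
#' @param statistic plot-height statistic (see \code{\link{plot_height}}).
#' @param alpha Bonferroni level for outlier screening.
#' @param h2_basis heritability denominator basis.
#' @return list: trial, heights (combined long table), rois, csm, georef
#'   (horizontal/vertical/criteria), genetics (per stage x platform:
#'   variance components, H2, BLUPs; plus spearman aerial-vs-ground),
#'   agreement, manifest (when writing).
#' @export
run_trial_pipeline <- function(config, out_dir = NULL, buffer_m = 0.1,
                               statistic = "mean_above_p75", alpha = 0.01,
                               h2_basis = "entry_mean") {
  if (is.character(config)) config <- read_config(config)
  trial <- simulate_trial(config)
  stages <- names(trial$dsm)

  csm <- lapply(trial$dsm, function(d) compute_csm(d, trial$terrain))
  rois <- build_rois(trial$layout, buffer_m = buffer_m)
  aerial <- extract_trial(csm, rois, trial$layout, statistic = statistic)
  heights <- rbind(
    cbind(trial$ground, n_pixels = NA_integer_, flag = "ok"),
    aerial)
  rownames(heights) <- NULL

  georef <- list(
    horizontal = horizontal_deltas(trial$targets, role = "checkpoint"),
    vertical = vertical_accuracy(trial$targets, csm[[1]],
                                 footprint_m = config$target_side_m * 0.6))
  georef$criteria <- check_accuracy_criteria(georef, gsd_m = config$cell_size_m)

  genetics <- list()
  for (st in stages) {
    for (pf in c("ground", "aerial")) {
      d <- heights[heights$stage == st & heights$platform == pf, ]
      fit <- fit_blup_model(d)
      h2 <- tryCatch(broad_sense_heritability(fit, n_rep = config$n_replicates,
                                              basis = h2_basis),
                     error = function(e) list(H2 = NA_real_, se = NA_real_,
                                              basis = h2_basis))
      genetics[[paste(st, pf, sep = ".")]] <-
        list(stage = st, platform = pf, sigma2 = fit$sigma2, H2 = h2$H2,
             H2_basis = h2$basis, blup = compute_blups(fit))
    }
    b_g <- genetics[[paste(st, "ground", sep = ".")]]$blup
    b_a <- genetics[[paste(st, "aerial", sep = ".")]]$blup
    m <- merge(b_g, b_a, by = "genotype", suffixes = c("_ground", "_aerial"))
    genetics[[paste(st, "spearman", sep = ".")]] <-
      tryCatch(spearman_with_test(m$blup_ground, m$blup_aerial),
               error = function(e) list(rho = NA_real_, p_value = NA_real_))
  }

  agr <- agreement_by_stage(heights, alpha = alpha)

  result <- list(trial = trial, heights = heights, rois = rois, csm = csm,
                 georef = georef, genetics = genetics, agreement = agr)
  if (!is.null(out_dir)) result$manifest <- write_pipeline_outputs(result, out_dir)
  result
}

#' @rdname run_trial_pipeline
#' @param result a \code{run_trial_pipeline} result.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial <- result$trial
  paths <- c(
    dtm = file.path(out_dir, "dtm.tif"),
    layout = file.path(out_dir, "layout.geojson"),
    targets = file.path(out_dir, "targets.csv"),
    truth = file.path(out_dir, "truth.csv"),
    heights = file.path(out_dir, "heights.csv"))
  write_elevation_raster(trial$terrain, paths[["dtm"]])
  write_layout_geojson(trial$layout, paths[["layout"]])
  utils::write.csv(trial$targets, paths[["targets"]], row.names = FALSE)
  utils::write.csv(trial$truth$plot_true_height_cm, paths[["truth"]],
                   row.names = FALSE)
  utils::write.csv(result$heights, paths[["heights"]], row.names = FALSE)
  for (st in names(trial$dsm)) {
    p1 <- file.path(out_dir, sprintf("dsm_%s.tif", gsub("[^A-Za-z0-9]", "", st)))
    p2 <- file.path(out_dir, sprintf("csm_%s.tif", gsub("[^A-Za-z0-9]", "", st)))
    write_elevation_raster(trial$dsm[[st]], p1)
    write_elevation_raster(result$csm[[st]], p2)
    paths[paste0("dsm_", st)] <- p1
    paths[paste0("csm_", st)] <- p2
  }
  report <- list(
    georef = list(
      horizontal = result$georef$horizontal[c("x", "y", "n_targets")],
      vertical = result$georef$vertical[c("slope", "intercept", "r_squared",
                                          "rmse_residual_m", "z")],
      criteria = result$georef$criteria),
    heritability = lapply(result$genetics, function(g)
      if (!is.null(g$H2)) list(stage = g$stage, platform = g$platform,
                               H2 = g$H2, sigma2 = as.list(g$sigma2)) else NULL),
    agreement = lapply(result$agreement$per_stage, unclass),
    rmse_dev = unclass(result$agreement$rmse_dev))
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  paths["report"] <- rp

  manifest <- list(
    seed = trial$config$seed,
    package_version = as.character(utils::packageVersion("phenoheight")),
    created = format(Sys.time(), tz = "UTC"),
    config = trial$config[setdiff(names(trial$config), "stage_mean_cm")],
    stage_mean_cm = as.list(trial$config$stage_mean_cm),
    files = lapply(stats::setNames(as.character(paths), names(paths)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
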