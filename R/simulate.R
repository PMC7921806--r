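# Synthetic trial generator: terrain, genotype truth, canopy surfaces, ground
# measurements, ground targets and pedigrees, all pure functions of
# (config, seed) so every downstream stage can be tested against known truth.

#' Simulate bare-soil terrain (DTM)
#'
#' Smoothed Gaussian random field: white noise on a coarse (2 m) lattice,
#' Gaussian-filtered, bilinearly upsampled to the working resolution and
#' amplitude-rescaled so the peak-to-peak relief equals
#' \code{terrain_relief_cm} exactly. A zero relief gives a perfectly flat
#' grid at \code{base_elevation_m}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return an \code{\link{elevation_grid}} covering the extent.
#' @export
simulate_terrain <- function(config) {
  cf <- config
  nc <- as.integer(ceiling(cf$extent_m[1] / cf$cell_size_m))
  nr <- as.integer(ceiling(cf$extent_m[2] / cf$cell_size_m))
  if (as.numeric(nr) * nc > 1e8)
    stop("extent/cell_size imply more than 1e8 cells")
  if (cf$terrain_relief_cm == 0) {
    m <- matrix(cf$base_elevation_m, nr, nc)
  } else {
    coarse <- 2  # meters
    cnc <- as.integer(ceiling(cf$extent_m[1] / coarse)) + 5L
    cnr <- as.integer(ceiling(cf$extent_m[2] / coarse)) + 5L
    z <- with_seed(derive_seed(cf$seed, "terrain"),
                   matrix(stats::rnorm(cnr * cnc), cnr, cnc))
    z <- gaussian_smooth(z, sigma = 1.5)
    cgrid <- elevation_grid(z, xmin = -coarse * 2.5, ymax = cf$extent_m[2] + coarse * 2.5,
                            cell_x = coarse)
    full <- elevation_grid(matrix(0, nr, nc), xmin = 0, ymax = nr * cf$cell_size_m,
                           cell_x = cf$cell_size_m)
    zf <- resample_onto(cgrid, full, method = "bilinear")$values
    zf <- (zf - min(zf)) / (max(zf) - min(zf)) - 0.5  # peak-to-peak exactly 1
    m <- cf$base_elevation_m + zf * (cf$terrain_relief_cm / 100)
  }
  elevation_grid(m, xmin = 0, ymax = nr * cf$cell_size_m, cell_x = cf$cell_size_m)
}

# separable Gaussian blur with edge renormalization (small matrices only)
gaussian_smooth <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(padded, k, sides = 2)[(r + 1):(r + n)]
  }
  m <- apply(m, 2, smooth1)
  t(apply(t(m), 2, smooth1))
}

#' Simulate true genetic and design effects
#'
#' Draws additive genotype, replicate and block effects for every growth
#' stage (all centered Normal with the configured SDs) and composes the
#' per-plot true canopy-top height: stage mean + genotype + replicate +
#' block effect, before any measurement or surface noise.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param layout a \code{\link{field_layout}}; defaults to
#'   \code{simulate_layout(config)}.
#' @return list of class \code{true_genetics}: \code{genotype_effects_cm},
#'   \code{replicate_effects_cm}, \code{block_effects_cm} (matrices, one
#'   column per stage) and \code{plot_true_height_cm} (data.frame plot x
#'   stage, long format).
#' @export
simulate_genotype_truth <- function(config, layout = simulate_layout(config)) {
  cf <- config
  stages <- names(cf$stage_mean_cm)
  genos <- sort(unique(layout$plots$genotype))
  reps <- sort(unique(layout$plots$rep))
  blocks <- unique(layout$plots[, c("rep", "block")])
  blocks <- blocks[order(blocks$rep, blocks$block), ]
  eff <- with_seed(derive_seed(cf$seed, "genetics"), {
    g <- matrix(stats::rnorm(length(genos) * length(stages), 0, cf$genotype_sd_cm),
                length(genos), dimnames = list(genos, stages))
    r <- matrix(stats::rnorm(length(reps) * length(stages), 0, cf$replicate_sd_cm),
                length(reps), dimnames = list(paste0("R", reps), stages))
    b <- matrix(stats::rnorm(nrow(blocks) * length(stages), 0, cf$block_sd_cm),
                nrow(blocks),
                dimnames = list(paste0("R", blocks$rep, "B", blocks$block), stages))
    list(g = g, r = r, b = b)
  })
  p <- layout$plots
  rows <- lapply(stages, function(st) {
    data.frame(plot_id = p$plot_id, genotype = p$genotype,
               rep = p$rep, block = p$block, stage = st,
               true_height_cm = cf$stage_mean_cm[[st]] +
                 eff$g[p$genotype, st] +
                 eff$r[paste0("R", p$rep), st] +
                 eff$b[paste0("R", p$rep, "B", p$block), st])
  })
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  structure(list(genotype_effects_cm = eff$g, replicate_effects_cm = eff$r,
                 block_effects_cm = eff$b, plot_true_height_cm = truth),
            class = "true_genetics")
}

#' Simulate a per-flight canopy surface (DSM)
#'
#' Builds the digital surface model for one growth stage on top of a terrain
#' grid. Within each plot's two bed footprints, per-culm canopy texture is
#' generated on a jittered grid along the four plant rows: each culm's height
#' is drawn around the plot's true height with SD \code{culm_sd_cm}, the
#' surface follows the nearest culm with valleys dipping (up to 1.5 x
#' \code{culm_sd_cm}) between culms, so the upper quantiles of plot pixels
#' track the canopy top while the plain mean sits below it. The canopy tapers
#' linearly to bare soil across the inter-bed furrow and stops at plot edges
#' (alleys are soil). Optional ground-target pillars are stamped in, then an
#' optional lateral wind blur and Normal elevation noise
#' (\code{surface_noise_sd_cm}) are applied.
#'
#' With all texture/noise SDs zero and no blur, the DSM inside bed footprints
#' equals terrain + true plot height exactly.
#'
#' @param terrain DTM \code{elevation_grid} from \code{\link{simulate_terrain}}.
#' @param layout \code{\link{field_layout}} in the same frame.
#' @param truth \code{true_genetics} from \code{\link{simulate_genotype_truth}}.
#' @param config the \code{\link{simulation_config}}.
#' @param stage growth-stage label, one of \code{names(config$stage_mean_cm)}.
#' @param targets optional target table from \code{\link{place_targets}};
#'   pillars are stamped (top = terrain + height) before noise.
#' @return DSM \code{elevation_grid}.
#' @export
simulate_canopy_surface <- function(terrain, layout, truth, config, stage,
                                    targets = NULL) {
  cf <- config
  if (!stage %in% names(cf$stage_mean_cm) ||
      !stage %in% truth$plot_true_height_cm$stage)
    stop("unknown growth stage: ", stage)
  tv <- terrain$values
  canopy <- matrix(0, nrow(tv), ncol(tv))
  cell <- terrain$cell_x
  xs <- grid_x_centers(terrain); ys <- grid_y_centers(terrain)

  th <- truth$plot_true_height_cm
  th <- th[th$stage == stage, ]
  rownames(th) <- th$plot_id

  bw <- cf$bed_width_m; ib <- cf$inter_bed_m
  row_x_local <- c(bw / 2 - cf$inter_row_m / 2, bw / 2 + cf$inter_row_m / 2,
                   bw + ib + bw / 2 - cf$inter_row_m / 2,
                   bw + ib + bw / 2 + cf$inter_row_m / 2)
  culm_spacing <- 0.06  # m along the row
  valley_depth <- 1.5   # valleys dip up to this multiple of culm_sd below culm tops
  furrow_taper <- 0.45 * ib  # canopy reaches soil this far into the furrow

  seed0 <- derive_seed(cf$seed, paste0("canopy-", stage))
  plots <- layout$plots
  n_culms_row <- max(1L, as.integer(floor(cf$plot_length_m / culm_spacing)))

  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    true_m <- th[p$plot_id, "true_height_cm"] / 100
    jj <- which(xs >= p$xmin & xs < p$xmax)
    ii <- which(ys > p$ymin & ys <= p$ymax)
    if (!length(jj) || !length(ii)) next
    lx <- xs[jj] - p$xmin          # local across-plot coordinate
    ly <- p$ymax - ys[ii]          # local along-plot coordinate

    culm <- with_seed(seed0 + i, list(
      h = matrix(true_m + stats::rnorm(4 * n_culms_row, 0, cf$culm_sd_cm / 100),
                 4, n_culms_row),
      jit = matrix(stats::runif(4 * n_culms_row, -0.015, 0.015), 4, n_culms_row)))

    # nearest row line and across-row distance, per column
    drow <- abs(outer(lx, row_x_local, "-"))
    ridx <- max.col(-drow, ties.method = "first")
    dx <- drow[cbind(seq_along(lx), ridx)]
    # canopy cover across the furrow: 1 in beds, linear to 0 inside furrow
    in_bed <- (lx <= bw) | (lx >= bw + ib)
    dfur <- pmin(abs(lx - bw), abs(lx - bw - ib))
    cover <- ifelse(in_bed, 1, pmax(0, 1 - dfur / furrow_taper))

    # nearest culm index along the row, per cell
    kidx <- pmin(pmax(as.integer(floor(ly / culm_spacing)) + 1L, 1L), n_culms_row)
    kmat <- matrix(kidx, length(ii), length(jj))
    rmat <- matrix(ridx, length(ii), length(jj), byrow = TRUE)
    cid <- cbind(as.vector(rmat), as.vector(kmat))
    hc <- matrix(culm$h[cid], length(ii), length(jj))
    ycent <- (kidx - 0.5) * culm_spacing
    dy <- matrix(ly - ycent, length(ii), length(jj)) -
      matrix(culm$jit[cid], length(ii), length(jj))
    dxm <- matrix(dx, length(ii), length(jj), byrow = TRUE)
    u2 <- (dxm^2 + dy^2) / (0.5 * culm_spacing)^2
    dip <- (cf$culm_sd_cm / 100) * valley_depth * pmin(u2, 1)
    covm <- matrix(cover, length(ii), length(jj), byrow = TRUE)
    canopy[ii, jj] <- pmax(canopy[ii, jj], pmax(hc - dip, 0) * covm)
  }

  dsm <- tv + canopy
  if (!is.null(targets)) {
    half <- cf$target_side_m / 2
    for (t in seq_len(nrow(targets))) {
      jj <- which(xs >= targets$surveyed_x[t] - half & xs < targets$surveyed_x[t] + half)
      ii <- which(ys > targets$surveyed_y[t] - half & ys <= targets$surveyed_y[t] + half)
      if (length(jj) && length(ii))
        dsm[ii, jj] <- tv[ii, jj] + targets$height_cm[t] / 100
    }
  }
  if (cf$wind_smear_px > 0) dsm <- box_blur(dsm, cf$wind_smear_px)
  if (cf$surface_noise_sd_cm > 0)
    dsm <- dsm + with_seed(derive_seed(cf$seed, paste0("noise-", stage)),
                           matrix(stats::rnorm(length(dsm), 0, cf$surface_noise_sd_cm / 100),
                                  nrow(dsm), ncol(dsm)))
  elevation_grid(dsm, xmin = terrain$xmin, ymax = terrain$ymax,
                 cell_x = terrain$cell_x, cell_y = terrain$cell_y,
                 nodata = terrain$nodata, crs = terrain$crs)
}

# mean filter with window 2r+1, replicate-padded edges
box_blur <- function(m, r) {
  pass <- function(mm) {
    n <- nrow(mm)
    idx <- pmin(pmax(outer(seq_len(n), (-r):r, "+"), 1L), n)
    out <- matrix(0, n, ncol(mm))
    for (k in seq_len(2 * r + 1)) out <- out + mm[idx[, k], , drop = FALSE]
    out / (2 * r + 1)
  }
  t(pass(t(pass(m))))
}

#' Simulate manual ground-truth height measurements
#'
#' Emulates the field protocol: per plot, the average of \code{n_culms}
#' random culms (each culm's height drawn around the plot's true height with
#' SD \code{culm_sd_cm}) measured with ruler error \code{measurement_sd_cm}.
#'
#' @inheritParams simulate_canopy_surface
#' @return data.frame: plot_id, genotype, rep, block, stage, platform
#'   ("ground"), ph_cm.
#' @export
simulate_ground_measurements <- function(layout, truth, config, stage) {
  cf <- config
  th <- truth$plot_true_height_cm
  th <- th[th$stage == stage, ]
  n <- nrow(th)
  ph <- with_seed(derive_seed(cf$seed, paste0("ground-", stage)), {
    culm_means <- vapply(th$true_height_cm, function(mu)
      mean(stats::rnorm(cf$n_culms, mu, cf$culm_sd_cm)), numeric(1))
    culm_means + stats::rnorm(n, 0, cf$measurement_sd_cm)
  })
  data.frame(plot_id = th$plot_id, genotype = th$genotype, rep = th$rep,
             block = th$block, stage = stage, platform = "ground", ph_cm = ph)
}

#' Place surveyed ground targets (GCPs and checkpoints)
#'
#' Distributes square target pillars around the trial margin: known heights
#' cycle through a 0-120 cm ladder, roles alternate between bundle-adjustment
#' GCPs and held-out checkpoints so both kinds cover the field. Measured
#' (image-derived) horizontal coordinates are the surveyed ones plus the
#' configured systematic shift and Normal noise. Raises an error if a target
#' footprint overlaps any plot polygon.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param layout optional \code{\link{field_layout}} for the overlap check.
#' @return data.frame: target_id, role ("gcp"/"checkpoint"), surveyed_x/y/z,
#'   height_cm, measured_x, measured_y.
#' @export
place_targets <- function(config, layout = NULL) {
  cf <- config
  n <- cf$n_gcp + cf$n_checkpoints
  w <- cf$extent_m[1]; h <- cf$extent_m[2]
  inset <- cf$margin_m / 2
  # evenly spaced stations along the margin ring, corner-started
  per <- 2 * (w - 2 * inset) + 2 * (h - 2 * inset)
  d <- (seq_len(n) - 1) * per / n
  pos <- t(vapply(d, function(s) {
    a <- w - 2 * inset; b <- h - 2 * inset
    if (s < a) c(inset + s, inset)
    else if (s < a + b) c(w - inset, inset + (s - a))
    else if (s < 2 * a + b) c(w - inset - (s - a - b), h - inset)
    else c(inset, h - inset - (s - 2 * a - b))
  }, numeric(2)))
  ladder <- c(0, 30, 60, 90, 120)
  heights <- ladder[(seq_len(n) - 1) %% length(ladder) + 1]
  role <- rep("checkpoint", n)
  if (cf$n_gcp > 0)
    role[round(seq(1, n, length.out = cf$n_gcp))] <- "gcp"
  # if rounding collapsed stations, top up deterministically
  short <- cf$n_gcp - sum(role == "gcp")
  if (short > 0) role[which(role == "checkpoint")[seq_len(short)]] <- "gcp"

  targets <- data.frame(target_id = sprintf("T%02d", seq_len(n)), role = role,
                        surveyed_x = pos[, 1], surveyed_y = pos[, 2],
                        surveyed_z = heights / 100, height_cm = heights)
  err <- with_seed(derive_seed(cf$seed, "targets"),
                   matrix(stats::rnorm(2 * n, 0, cf$georef_noise_sd_cm / 100), n))
  targets$measured_x <- targets$surveyed_x + cf$georef_shift_cm / 100 + err[, 1]
  targets$measured_y <- targets$surveyed_y + cf$georef_shift_cm / 100 + err[, 2]

  if (!is.null(layout)) {
    half <- cf$target_side_m / 2
    for (i in seq_len(nrow(targets)))
      for (pg in layout$polygons) {
        bb <- polygon_bbox(pg)
        if (targets$surveyed_x[i] + half > bb["xmin"] &&
            targets$surveyed_x[i] - half < bb["xmax"] &&
            targets$surveyed_y[i] + half > bb["ymin"] &&
            targets$surveyed_y[i] - half < bb["ymax"])
          stop("target ", targets$target_id[i], " overlaps a plot polygon")
      }
  }
  targets
}

#' Simulate a breeding pedigree
#'
#' Founders are unrelated and non-inbred; each cross samples two distinct
#' parents among all previously created individuals, so the pedigree is
#' acyclic with parents preceding offspring.
#'
#' @param n_founders number of founder individuals.
#' @param n_crosses number of derived individuals.
#' @param seed integer seed.
#' @return data.frame: id, parent1, parent2 ("0" = unknown/founder).
#' @export
simulate_pedigree <- function(n_founders, n_crosses, seed = 1L) {
  stopifnot(n_founders >= 1, n_crosses >= 0)
  if (n_crosses > 0 && n_founders < 2)
    stop("crosses need at least two founders")
  ids <- sprintf("I%03d", seq_len(n_founders + n_crosses))
  p1 <- p2 <- rep("0", n_founders + n_crosses)
  if (n_crosses > 0) {
    with_seed(derive_seed(seed, "pedigree"), {
      for (k in seq_len(n_crosses)) {
        i <- n_founders + k
        par <- sample.int(i - 1L, 2L)
        p1[i] <- ids[par[1]]; p2[i] <- ids[par[2]]
      }
    })
  }
  data.frame(id = ids, parent1 = p1, parent2 = p2)
}
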