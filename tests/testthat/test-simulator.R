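test_that("terrain: zero relief is flat, seeds reproduce, relief amplitude is honored", {
  cf0 <- tiny_config(terrain_relief_cm = 0)
  t0 <- simulate_terrain(cf0)
  expect_true(all(t0$values == cf0$base_elevation_m))

  cf <- tiny_config(seed = 9)
  expect_identical(simulate_terrain(cf)$values, simulate_terrain(cf)$values)

  ranges <- vapply(1:20, function(s) {
    tr <- simulate_terrain(tiny_config(seed = s, terrain_relief_cm = 10))
    diff(range(tr$values)) * 100
  }, numeric(1))
  expect_true(all(ranges >= 5 & ranges <= 20))
})

test_that("terrain rejects configs implying excessive rasters", {
  cf <- tiny_config()
  cf$extent_m <- c(5000, 5000)  # bypass constructor to hit the guard
  cf$cell_size_m <- 0.01
  expect_error(simulate_terrain(cf), "1e8|cells")
})

test_that("layout realizes a resolvable design with non-overlapping plots", {
  cf <- simulation_config(seed = 2, n_genotypes = 150, n_replicates = 2,
                          n_blocks_per_rep = 30, cell_size_m = 0.05)
  lay <- simulate_layout(cf)
  expect_equal(nrow(lay$plots), 300)
  # each genotype exactly once per replicate
  tab <- table(lay$plots$genotype, lay$plots$rep)
  expect_true(all(tab == 1))
  # 5 genotypes per incomplete block
  expect_true(all(table(lay$plots$rep, lay$plots$block) == 5))
  # non-overlap: every plot pair's rectangles are disjoint
  p <- lay$plots
  ov <- 0L
  for (i in seq_len(nrow(p) - 1)) {
    jj <- seq(i + 1, nrow(p))
    hit <- p$xmin[jj] < p$xmax[i] & p$xmax[jj] > p$xmin[i] &
           p$ymin[jj] < p$ymax[i] & p$ymax[jj] > p$ymin[i]
    ov <- ov + sum(hit)
  }
  expect_identical(ov, 0L)
  # plot polygons are two-bed footprints
  expect_equal(unique(round(p$xmax - p$xmin, 9)),
               2 * cf$bed_width_m + cf$inter_bed_m)
  # plot areas total the expected tiled fraction of the extent
  total_area <- sum((p$xmax - p$xmin) * (p$ymax - p$ymin))
  expect_equal(total_area, 300 * 1.96 * 4)
  expect_lt(total_area, prod(cf$extent_m))
})

test_that("single-plot layout and indivisible block sizes behave per contract", {
  cf1 <- simulation_config(seed = 1, n_genotypes = 1, n_replicates = 1,
                           n_blocks_per_rep = 1, cell_size_m = 0.05)
  expect_equal(nrow(simulate_layout(cf1)$plots), 1)
  cf_bad <- simulation_config(seed = 1, n_genotypes = 10, n_replicates = 2,
                              n_blocks_per_rep = 3, cell_size_m = 0.05)
  expect_error(simulate_layout(cf_bad), "divide")
})

test_that("genotype effects have the configured spread and zero-SD degenerates to zero", {
  cf <- simulation_config(seed = 4, n_genotypes = 10000, n_replicates = 1,
                          n_blocks_per_rep = 100, cell_size_m = 1,
                          genotype_sd_cm = 5, stage_mean_cm = c(M = 90))
  tr <- simulate_genotype_truth(cf)
  s <- sd(tr$genotype_effects_cm[, "M"])
  expect_true(abs(s - 5) < 0.15)

  cf0 <- tiny_config(genotype_sd_cm = 0)
  tr0 <- simulate_genotype_truth(cf0)
  expect_true(all(tr0$genotype_effects_cm == 0))
})

test_that("plot truth composes stage mean + genotype + replicate + block effects", {
  cf <- tiny_config(seed = 6)
  lay <- simulate_layout(cf)
  tr <- simulate_genotype_truth(cf, lay)
  th <- tr$plot_true_height_cm
  for (i in sample(nrow(th), 10)) {
    row <- th[i, ]
    expect_equal(row$true_height_cm,
                 cf$stage_mean_cm[[row$stage]] +
                   tr$genotype_effects_cm[row$genotype, row$stage] +
                   tr$replicate_effects_cm[paste0("R", row$rep), row$stage] +
                   tr$block_effects_cm[paste0("R", row$rep, "B", row$block), row$stage])
  }
  # stage ordering of the defaults: E+40 < B < M < A+7 on average
  cfd <- simulation_config(seed = 1, n_genotypes = 20, n_replicates = 2,
                           n_blocks_per_rep = 4, cell_size_m = 0.05)
  trd <- simulate_genotype_truth(cfd)
  mu <- tapply(trd$plot_true_height_cm$true_height_cm,
               trd$plot_true_height_cm$stage, mean)
  expect_true(mu[["E+40"]] < mu[["B"]] && mu[["B"]] < mu[["M"]] &&
                mu[["M"]] < mu[["A+7"]])
})

test_that("noiseless canopy surface equals true height inside beds and dips in furrows", {
  cf <- tiny_config(noiseless = TRUE, terrain_relief_cm = 5)
  lay <- simulate_layout(cf)
  ter <- simulate_terrain(cf)
  tr <- simulate_genotype_truth(cf, lay)
  dsm <- simulate_canopy_surface(ter, lay, tr, cf, "M")
  canopy <- dsm$values - ter$values
  th <- tr$plot_true_height_cm
  th <- th[th$stage == "M", ]
  xs <- grid_x_centers(dsm); ys <- grid_y_centers(dsm)
  for (i in c(1, 5, nrow(lay$plots))) {
    p <- lay$plots[i, ]
    truth_m <- th$true_height_cm[th$plot_id == p$plot_id] / 100
    # bed interior: a point centered on bed 1
    jj <- which(xs > p$xmin + 0.1 & xs < p$xmin + cf$bed_width_m - 0.1)
    ii <- which(ys > p$ymin + 0.2 & ys < p$ymax - 0.2)
    expect_true(all(abs(canopy[ii, jj] - truth_m) < 1e-12))
    # furrow centerline: canopy below a quarter of the plot height
    fj <- which(abs(xs - (p$xmin + cf$bed_width_m + cf$inter_bed_m / 2)) <
                  cf$cell_size_m)
    expect_true(all(canopy[ii, fj] < 0.25 * truth_m))
  }
  # alleys are bare soil
  expect_true(all(abs(canopy[ys > max(lay$plots$ymax) + 0.1, ]) < 1e-12))
})

test_that("canopy height stays above soil up to the noise tail bound", {
  cf <- tiny_config(seed = 8)
  lay <- simulate_layout(cf)
  ter <- simulate_terrain(cf)
  tr <- simulate_genotype_truth(cf, lay)
  dsm <- simulate_canopy_surface(ter, lay, tr, cf, "B")
  canopy <- dsm$values - ter$values
  sd_m <- cf$surface_noise_sd_cm / 100
  # pointwise the soil floor is violated only by the Normal noise: over ~1e6
  # cells the extreme deviates reach ~5 sd, never 6, and the 3.5 sd tail
  # fraction stays at its Normal level
  expect_gt(min(canopy), -6 * sd_m)
  expect_lt(mean(canopy < -3.5 * sd_m), 1e-3)
})

test_that("unknown growth stage is rejected", {
  cf <- tiny_config()
  lay <- simulate_layout(cf)
  ter <- simulate_terrain(cf)
  tr <- simulate_genotype_truth(cf, lay)
  expect_error(simulate_canopy_surface(ter, lay, tr, cf, "flowering"),
               "unknown growth stage")
})

test_that("ground measurements: exact under zero noise, SE of the 4-culm mean otherwise", {
  cf0 <- tiny_config(noiseless = TRUE)
  lay0 <- simulate_layout(cf0)
  tr0 <- simulate_genotype_truth(cf0, lay0)
  g0 <- simulate_ground_measurements(lay0, tr0, cf0, "M")
  th0 <- tr0$plot_true_height_cm
  th0 <- th0[th0$stage == "M", ]
  expect_equal(g0$ph_cm, th0$true_height_cm)

  # culm_sd = 4, 4 culms, no ruler error: SD of (mean - truth) ~ 4/sqrt(4) = 2
  cf <- simulation_config(seed = 3, n_genotypes = 100, n_replicates = 4,
                          n_blocks_per_rep = 10, cell_size_m = 0.1,
                          plot_length_m = 2, culm_sd_cm = 4,
                          measurement_sd_cm = 0, stage_mean_cm = c(M = 90))
  lay <- simulate_layout(cf)
  tr <- simulate_genotype_truth(cf, lay)
  g <- simulate_ground_measurements(lay, tr, cf, "M")
  th <- tr$plot_true_height_cm[tr$plot_true_height_cm$stage == "M", ]
  err_sd <- sd(g$ph_cm - th$true_height_cm)
  expect_true(abs(err_sd - 2) < 0.25)  # 400 plots: ~3.5 SEs of a sample SD
})

test_that("targets: counts, roles, ladder heights, pillar stamping and overlap guard", {
  cf <- tiny_config(georef_noise_sd_cm = 0)
  lay <- simulate_layout(cf)
  tg <- place_targets(cf, lay)
  expect_equal(sum(tg$role == "checkpoint"), 11L)
  expect_equal(sum(tg$role == "gcp"), 9L)
  expect_true(all(tg$height_cm %in% c(0, 30, 60, 90, 120)))
  expect_equal(tg$measured_x, tg$surveyed_x)

  ter <- simulate_terrain(tiny_config(noiseless = TRUE))
  tr <- simulate_genotype_truth(tiny_config(noiseless = TRUE), lay)
  dsm <- simulate_canopy_surface(ter, lay, tr, tiny_config(noiseless = TRUE),
                                 "M", targets = tg)
  csm <- compute_csm(dsm, ter)
  for (i in c(1, 10)) {
    got <- sample_target_height(csm, tg$surveyed_x[i], tg$surveyed_y[i],
                                footprint_m = cf$target_side_m * 0.6)
    expect_equal(got$height_m, tg$height_cm[i] / 100)
  }
  # a target on top of a plot is refused: a layout whose single plot spans
  # the whole extent necessarily collides with the margin ring
  big <- field_layout(
    data.frame(plot_id = "P0001", genotype = "G001", rep = 1L, block = 1L,
               xmin = 0, xmax = cf$extent_m[1], ymin = 0, ymax = cf$extent_m[2]),
    list(P0001 = rect_polygon(0, 0, cf$extent_m[1], cf$extent_m[2])))
  expect_error(place_targets(cf, big), "overlaps")
})

test_that("pedigree simulation: founders, acyclicity, reproducibility, sib structure", {
  p <- simulate_pedigree(5, 10, seed = 3)
  expect_equal(nrow(p), 15)
  expect_true(all(p$parent1[1:5] == "0"))
  # parents precede offspring
  idx <- setNames(seq_len(nrow(p)), p$id)
  for (i in 6:15) {
    expect_lt(idx[p$parent1[i]], i)
    expect_lt(idx[p$parent2[i]], i)
    expect_true(p$parent1[i] != p$parent2[i])
  }
  expect_identical(simulate_pedigree(5, 10, seed = 3), p)
  expect_false(identical(simulate_pedigree(5, 10, seed = 4), p))
})

test_that("simulator outputs are pure functions of (config, seed)", {
  cf <- tiny_config(seed = 123)
  a <- simulate_trial(cf, stages = "M")
  b <- simulate_trial(cf, stages = "M")
  expect_identical(a$terrain$values, b$terrain$values)
  expect_identical(a$dsm$M$values, b$dsm$M$values)
  expect_identical(a$ground, b$ground)
  expect_identical(a$targets, b$targets)
})
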