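test_that("build_rois shrinks rectangles by the buffer on every side", {
  lay <- simulate_layout(tiny_config())
  rois <- build_rois(lay, buffer_m = 0.1)
  p <- lay$plots[1, ]
  bb <- polygon_bbox(rois[[p$plot_id]]$polygon)
  expect_equal(unname(bb), c(p$xmin + 0.1, p$xmax - 0.1, p$ymin + 0.1,
                             p$ymax - 0.1))
  # a 1.96 x 4 m plot with 0.1 m buffer: ROI 1.76 x 3.8 m, area 6.688 m2
  poly <- rect_polygon(0, 0, 1.96, 4)
  inner <- buffer_inward(poly, 0.1)
  expect_equal(polygon_area(inner), 1.76 * 3.8)
  # zero buffer is the identity
  r0 <- build_rois(lay, buffer_m = 0)
  expect_equal(r0[[1]]$polygon, r0[[1]]$source_polygon)
  # a collapsing buffer names the plots
  expect_error(build_rois(lay, buffer_m = 1.1), "P0001")
})

test_that("extract_pixels matches exhaustive center-in-polygon enumeration", {
  csm <- random_grid(40, 40, seed = 11, xmin = 0, ymax = 8, cell = 0.2,
                     na_frac = 0.05)
  set.seed(21)
  for (k in 1:20) {
    poly <- random_convex_polygon(c(0.5, 7.5), c(0.5, 7.5))
    got <- sort(extract_pixels(csm, poly)$values)
    want <- sort(oracle_extract(csm, poly))
    expect_equal(got, want)
  }
})

test_that("extract_pixels handles exact covers, empty overlaps and nodata", {
  csm <- elevation_grid(matrix(1, 10, 10), xmin = 0, ymax = 10, cell_x = 1)
  # interior rectangle strictly containing a 3x3 block of centers
  s <- extract_pixels(csm, rect_polygon(1.9, 1.9, 5.1, 5.1))
  expect_equal(s$n_pixels, 9L)
  expect_true(all(s$values == 1))
  # fully outside the extent
  expect_equal(extract_pixels(csm, rect_polygon(50, 50, 60, 60))$n_pixels, 0L)
  # nodata cells are excluded (row 7 col 4 has its center at x=3.5, y=3.5)
  csm$values[7, 4] <- NA
  expect_equal(extract_pixels(csm, rect_polygon(1.9, 1.9, 5.1, 5.1))$n_pixels, 8L)
})

test_that("plot_height: mean-above-p75 on 1..100 equals 88 under linear-interpolation percentiles", {
  s <- structure(list(plot_id = "p", values = (1:100) / 100, n_pixels = 100L),
                 class = "pixel_sample")
  out <- plot_height(s, "mean_above_p75")
  # q75 = 75.25 by linear interpolation; mean of {76..100} = 88
  expect_equal(out$value_cm, 88)
  expect_equal(plot_height(s, "mean")$value_cm, mean(1:100))
  expect_equal(plot_height(s, "median")$value_cm, 50.5)
  expect_equal(plot_height(s, "p90")$value_cm,
               100 * quantile((1:100) / 100, 0.9, names = FALSE))
})

test_that("plot_height degenerate cases: constant sample, ties at the top, too few pixels", {
  const <- structure(list(plot_id = "p", values = rep(0.8, 40), n_pixels = 40L),
                     class = "pixel_sample")
  expect_equal(plot_height(const)$value_cm, 80)
  # >25% of values tied at the maximum: strict-upper set empty, falls back to
  # the values at/above the threshold, i.e. the plateau height
  plateau <- structure(list(plot_id = "p",
                            values = c(rep(0.9, 30), runif(10, 0.1, 0.5)),
                            n_pixels = 40L), class = "pixel_sample")
  expect_equal(plot_height(plateau)$value_cm, 90)
  few <- structure(list(plot_id = "p", values = c(0.1, 0.2), n_pixels = 2L),
                   class = "pixel_sample")
  out <- plot_height(few)
  expect_true(is.na(out$value_cm))
  expect_identical(out$flag, "too_few_pixels")
  expect_equal(plot_height(few, "mean", min_pixels = 1L)$value_cm, 15)
})

test_that("threshold ordering holds: mean_above_p75 >= p75 >= median on any sample", {
  set.seed(31)
  for (k in 1:50) {
    v <- switch(1 + k %% 3, rnorm(200, 1, 0.2), rexp(200), runif(50))
    s <- structure(list(plot_id = "p", values = v, n_pixels = length(v)),
                   class = "pixel_sample")
    m75 <- plot_height(s, min_pixels = 10L)$value_cm
    q75 <- 100 * quantile(v, 0.75, names = FALSE)
    med <- plot_height(s, "median", min_pixels = 10L)$value_cm
    expect_gte(m75, q75)
    expect_gte(q75, med)
  }
})

test_that("increasing the buffer never increases the pixel count", {
  cf <- tiny_config(seed = 14)
  trial <- simulate_trial(cf, stages = "M")
  csm <- compute_csm(trial$dsm$M, trial$terrain)
  lay <- trial$layout
  counts <- sapply(c(0, 0.05, 0.1, 0.2, 0.4), function(b) {
    rois <- build_rois(lay, buffer_m = b)
    extract_pixels(csm, rois[[1]])$n_pixels
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("extract_trial: cardinality, ordering, determinism", {
  cf <- tiny_config(seed = 15)
  trial <- simulate_trial(cf)
  csm <- lapply(trial$dsm, function(d) compute_csm(d, trial$terrain))
  rois <- build_rois(trial$layout)
  tbl <- extract_trial(csm, rois, trial$layout)
  expect_equal(nrow(tbl), nrow(trial$layout$plots) * 2)  # 2 stages configured
  expect_true(all(tbl$flag == "ok"))
  expect_true(!is.unsorted(tbl$plot_id[tbl$stage == "M"]))
  expect_identical(extract_trial(csm, rois, trial$layout), tbl)
})

test_that("restricted mean tracks the canopy top better than the plain mean", {
  cf <- demo_config(seed = 16, stage_mean_cm = c(M = 90))
  trial <- simulate_trial(cf)
  csm <- list(M = compute_csm(trial$dsm$M, trial$terrain))
  rois <- build_rois(trial$layout)
  th <- trial$truth$plot_true_height_cm
  t75 <- extract_trial(csm, rois, trial$layout, statistic = "mean_above_p75")
  tmn <- extract_trial(csm, rois, trial$layout, statistic = "mean")
  m75 <- merge(t75, th[, c("plot_id", "stage", "true_height_cm")])
  mmn <- merge(tmn, th[, c("plot_id", "stage", "true_height_cm")])
  bias75 <- mean(m75$ph_cm - m75$true_height_cm)
  biasmn <- mean(mmn$ph_cm - mmn$true_height_cm)
  expect_lt(abs(bias75), abs(biasmn))
})
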