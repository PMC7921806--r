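make_targets <- function(dx, dy) {
  n <- length(dx)
  data.frame(target_id = sprintf("T%02d", 1:n), role = "checkpoint",
             surveyed_x = seq_len(n), surveyed_y = seq_len(n) * 2,
             measured_x = seq_len(n) + dx, measured_y = seq_len(n) * 2 + dy)
}

test_that("horizontal deltas: zero error, constant shift, hand-computed RMSE", {
  r0 <- horizontal_deltas(make_targets(rep(0, 5), rep(0, 5)))
  expect_equal(unname(r0$x[c("mean", "sd", "rmse")]), c(0, 0, 0))

  r1 <- horizontal_deltas(make_targets(rep(0.015, 6), rep(0, 6)))
  expect_equal(unname(r1$x["mean"]), 0.015)
  expect_equal(unname(r1$x["sd"]), 0)
  expect_equal(unname(r1$x["rmse"]), 0.015)

  r2 <- horizontal_deltas(make_targets(c(0.03, -0.04), c(0, 0)))
  expect_equal(unname(r2$x["rmse"]), sqrt((0.0009 + 0.0016) / 2))
  expect_equal(unname(r2$x["mean"]), -0.005)
})

test_that("RMSE^2 = mean^2 + SD^2 holds exactly with the population convention", {
  set.seed(7)
  for (k in 1:100) {
    d <- rnorm(sample(3:30, 1), sd = runif(1, 0.001, 0.1))
    t <- make_targets(d, rev(d))
    r <- horizontal_deltas(t)
    for (ax in c("x", "y")) {
      expect_equal(r[[ax]][["rmse"]]^2,
                   r[[ax]][["mean"]]^2 + r[[ax]][["sd"]]^2, tolerance = 1e-12)
      expect_gte(r[[ax]][["rmse"]], abs(r[[ax]][["mean"]]))
    }
  }
})

test_that("sample SD convention is available and larger than population SD", {
  t <- make_targets(c(0.01, 0.02, 0.04), rep(0, 3))
  rp <- horizontal_deltas(t, sd_convention = "population")
  rs <- horizontal_deltas(t, sd_convention = "sample")
  expect_equal(rs$x[["sd"]], sd(c(0.01, 0.02, 0.04)))
  expect_gt(rs$x[["sd"]], rp$x[["sd"]])
})

test_that("no usable checkpoints is an explicit error", {
  t <- make_targets(rep(0, 3), rep(0, 3))
  t$role <- "gcp"
  expect_error(horizontal_deltas(t), "checkpoint")
})

pillar_csm <- function(heights_m, noise_sd = 0, seed = 1, cell = 0.02) {
  # pillars in a row, 0.4 m targets spaced 1 m apart on a 0-height floor
  n <- length(heights_m)
  nr <- as.integer(1 / cell)
  ncl <- as.integer(n / cell)
  set.seed(seed)
  m <- matrix(0, nr, ncl)
  xs <- (seq_len(ncl) - 0.5) * cell
  targets <- data.frame(target_id = sprintf("T%02d", 1:n), role = "checkpoint",
                        surveyed_x = seq_len(n) - 0.5, surveyed_y = 0.5,
                        surveyed_z = heights_m)
  for (i in seq_len(n)) {
    jj <- which(abs(xs - targets$surveyed_x[i]) <= 0.2)
    m[, jj] <- heights_m[i]
  }
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  list(csm = elevation_grid(m, xmin = 0, ymax = 1, cell_x = cell),
       targets = targets)
}

test_that("vertical accuracy on noiseless pillars is an exact 1:1 fit", {
  p <- pillar_csm(c(0, 0.3, 0.6, 0.9, 1.2))
  r <- vertical_accuracy(p$targets, p$csm, footprint_m = 0.2)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmse_residual_m, 0)
  expect_equal(unname(r$z["rmse"]), 0)
})

test_that("vertical accuracy tolerates tied heights but rejects zero range", {
  p <- pillar_csm(c(0.5, 0.5, 0.2, 0.9))
  r <- vertical_accuracy(p$targets, p$csm, footprint_m = 0.2)
  expect_equal(r$slope, 1)
  flat <- pillar_csm(rep(0.5, 4))
  expect_error(vertical_accuracy(flat$targets, flat$csm, footprint_m = 0.2),
               "zero range")
})

test_that("R-squared of the vertical fit equals the squared Pearson correlation", {
  p <- pillar_csm(c(0, 0.3, 0.6, 0.9, 1.2), noise_sd = 0.01, seed = 5)
  r <- vertical_accuracy(p$targets, p$csm, footprint_m = 0.2)
  expect_equal(r$r_squared,
               cor(r$table$surveyed_z, r$table$measured_z)^2, tolerance = 1e-12)
})

test_that("GSD-multiple criteria: 2x horizontal and 3x vertical boundaries", {
  rep_h <- structure(list(x = c(mean = 0, sd = 0.033, rmse = 0.033),
                          y = c(mean = 0, sd = 0.010, rmse = 0.010)),
                     class = "georef_report")
  out <- check_accuracy_criteria(rep_h, gsd_m = 0.017)
  expect_true(out$pass[out$axis == "x"])   # 3.3 <= 2 x 1.7
  expect_false(out$pass_strict[out$axis == "x"])
  expect_true(out$pass_strict[out$axis == "y"])

  rep_z <- structure(list(z = c(mean = 0, sd = 0.022, rmse = 0.022)),
                     class = "georef_report")
  out_z <- check_accuracy_criteria(rep_z, gsd_m = 0.007)
  expect_false(out_z$pass)                 # 2.2 > 3 x 0.7
  out_z2 <- check_accuracy_criteria(rep_z, gsd_m = 0.0074)
  expect_true(out_z2$pass)
  # SD exactly at the threshold passes; zero SD passes any gsd
  rep_b <- structure(list(z = c(mean = 0, sd = 0.021, rmse = 0.021)),
                     class = "georef_report")
  expect_true(check_accuracy_criteria(rep_b, gsd_m = 0.007)$pass)
  rep_0 <- structure(list(z = c(mean = 0, sd = 0, rmse = 0)),
                     class = "georef_report")
  expect_true(check_accuracy_criteria(rep_0, gsd_m = 1e-9)$pass)
})
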