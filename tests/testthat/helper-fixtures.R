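# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as naive re-implementations (loops, direct formulas)
# so they stay independent of the package's vectorized code paths.

# small trial configs ---------------------------------------------------

tiny_config <- function(seed = 1, noiseless = FALSE, ...) {
  args <- list(seed = seed, n_genotypes = 12L, n_replicates = 2L,
               n_blocks_per_rep = 3L, plot_length_m = 2, cell_size_m = 0.03,
               stage_mean_cm = c(B = 85, M = 90))
  if (noiseless)
    args <- utils::modifyList(args, list(terrain_relief_cm = 0, culm_sd_cm = 0,
                                         measurement_sd_cm = 0,
                                         surface_noise_sd_cm = 0,
                                         georef_noise_sd_cm = 0))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

demo_config <- function(seed = 1, ...) {
  do.call(simulation_config,
          utils::modifyList(list(seed = seed, n_genotypes = 50L,
                                 n_replicates = 2L, n_blocks_per_rep = 10L,
                                 plot_length_m = 2, cell_size_m = 0.03), list(...)))
}

random_grid <- function(nr, nc, seed, xmin = 0, ymax = nr * 0.5, cell = 0.5,
                        na_frac = 0) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, 40, 2), nr, nc)
  if (na_frac > 0) m[runif(nr * nc) < na_frac] <- NA
  elevation_grid(m, xmin = xmin, ymax = ymax, cell_x = cell)
}

# independent oracles ----------------------------------------------------

# elementwise CSM subtraction by explicit double loop
oracle_csm <- function(dsm, dtm) {
  out <- matrix(NA_real_, nrow(dsm$values), ncol(dsm$values))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    a <- dsm$values[i, j]; b <- dtm$values[i, j]
    if (!is.na(a) && !is.na(b)) out[i, j] <- a - b
  }
  out
}

# point-in-polygon by the winding-number algorithm (different algorithm from
# the package's even-odd ray casting)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && is_left > 0) wn <- wn + 1
    } else {
      if (y2 <= py && is_left < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# exhaustive enumeration of in-ROI cell values over every cell center
oracle_extract <- function(csm, poly) {
  xs <- grid_x_centers(csm); ys <- grid_y_centers(csm)
  vals <- numeric(0)
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    if (oracle_point_in_polygon(xs[j], ys[i], poly)) {
      v <- csm$values[i, j]
      if (!is.na(v)) vals <- c(vals, v)
    }
  }
  vals
}

# random convex polygon (convex hull of random points) inside a box
random_convex_polygon <- function(xlim, ylim, n_pts = 8) {
  px <- runif(n_pts, xlim[1], xlim[2]); py <- runif(n_pts, ylim[1], ylim[2])
  h <- grDevices::chull(px, py)
  cbind(x = px[rev(h)], y = py[rev(h)])  # chull returns clockwise; reverse to CCW
}

# closed-form REML for the balanced one-way random-effects layout
oracle_oneway_reml <- function(y, grp) {
  n_per <- as.integer(table(grp)[1])
  a <- anova(stats::lm(y ~ grp))
  msb <- a[1, "Mean Sq"]; msw <- a[2, "Mean Sq"]
  c(group = max(0, (msb - msw) / n_per), residual = msw)
}

# alpha-lattice response simulated straight from the linear model (no rasters)
simulate_lattice_response <- function(seed, n_gen = 150, n_rep = 2, n_block = 30,
                                      mu = 90, sg = 5, sb = 2, se = 3, sr = 0) {
  set.seed(seed)
  k <- n_gen / n_block
  d <- expand.grid(genotype = sprintf("G%03d", seq_len(n_gen)),
                   rep = seq_len(n_rep))
  # resolvable blocking: random permutation of genotypes into blocks per rep
  d$block <- NA_integer_
  for (r in seq_len(n_rep))
    d$block[d$rep == r] <- (order(sample.int(n_gen)) - 1L) %/% k + 1L
  g <- rnorm(n_gen, 0, sg); names(g) <- sprintf("G%03d", seq_len(n_gen))
  rv <- rnorm(n_rep, 0, sr)
  b <- rnorm(n_rep * n_block, 0, sb)
  dim(b) <- c(n_rep, n_block)
  d$ph_cm <- mu + g[as.character(d$genotype)] + rv[d$rep] +
    b[cbind(d$rep, d$block)] + rnorm(nrow(d), 0, se)
  d
}
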