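test_that("REML matches the closed form on balanced one-way layouts", {
  for (s in 1:5) {
    set.seed(s)
    grp <- factor(rep(1:50, each = 4))
    y <- rnorm(50, 0, 3)[grp] + rnorm(200, 0, 2)
    d <- data.frame(grp = grp, y = y)
    fit <- fit_reml(d, "y", random = "grp")
    want <- oracle_oneway_reml(y, grp)
    expect_equal(fit$sigma2[["grp"]], want[["group"]], tolerance = 1e-6)
    expect_equal(fit$sigma2[["residual"]], want[["residual"]], tolerance = 1e-6)
  }
})

test_that("an all-equal response gives zero variances and the constant mean", {
  d <- data.frame(g = factor(rep(1:10, 3)), y = 5)
  fit <- fit_reml(d, "y", random = "g")
  expect_true(all(fit$sigma2 == 0))
  expect_equal(unname(fit$beta["(Intercept)"]), 5)
})

test_that("the REML optimum dominates random admissible parameter points", {
  set.seed(77)
  grp <- factor(rep(1:30, each = 4))
  y <- rnorm(30, 0, 3)[grp] + rnorm(120, 0, 2)
  fit <- fit_reml(data.frame(grp = grp, y = y), "y", random = "grp")
  opt <- reml_loglik_at(fit, pmax(fit$sigma2, 1e-8))
  worse <- vapply(1:200, function(k) {
    reml_loglik_at(fit, c(runif(1, 0.01, 30), runif(1, 0.01, 30)))
  }, numeric(1))
  expect_true(all(opt >= worse - 1e-7))
})

test_that("REML agrees with lme4 on an unbalanced two-factor layout", {
  skip_if_not_installed("lme4")
  set.seed(13)
  d <- expand.grid(genotype = sprintf("G%02d", 1:40), rep = factor(1:3))
  d$block <- factor((as.integer(d$genotype) - 1) %/% 8 + 1)
  d$y <- 50 + rnorm(40, 0, 4)[as.integer(d$genotype)] +
    rnorm(3, 0, 1)[as.integer(d$rep)] + rnorm(nrow(d), 0, 2)
  d <- d[-sample(nrow(d), 10), ]  # unbalance
  fit <- fit_reml(d, "y", random = c("genotype", "rep"))
  lf <- lme4::lmer(y ~ 1 + (1 | genotype) + (1 | rep), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sigma2[["genotype"]],
               vc$vcov[vc$grp == "genotype"], tolerance = 1e-4)
  expect_equal(fit$sigma2[["residual"]],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  expect_equal(unname(fit$beta["(Intercept)"]),
               unname(lme4::fixef(lf)[1]), tolerance = 1e-5)
})

test_that("rank-deficient fixed designs raise an error naming aliased terms", {
  d <- data.frame(g = factor(rep(1:5, 4)), dup = factor(rep(1:5, 4)),
                  r = factor(rep(1:4, each = 5)))
  d$y <- rnorm(20)
  expect_error(fit_reml(d, "y", fixed = c("g", "dup"), random = "r"),
               "rank deficient.*dup")
})

test_that("BLUEs: zero-noise recovery, shift equivariance, replicate relabeling", {
  d <- expand.grid(genotype = sprintf("G%02d", 1:10), rep = factor(1:2),
                   KEEP.OUT.ATTRS = FALSE)
  d$block <- factor(rep(1:2, each = 5)[as.integer(d$genotype)])
  mu_g <- seq(80, 98, by = 2); names(mu_g) <- sprintf("G%02d", 1:10)
  d$ph_cm <- mu_g[as.character(d$genotype)]
  fit <- fit_blue_model(d)
  blue <- compute_blues(fit)
  expect_equal(blue$blue, unname(mu_g[blue$genotype]), tolerance = 1e-8)

  d2 <- d; d2$ph_cm <- d$ph_cm + 7
  blue2 <- compute_blues(fit_blue_model(d2))
  expect_equal(blue2$blue, blue$blue + 7, tolerance = 1e-8)

  d3 <- d; d3$rep <- factor(3 - as.integer(as.character(d3$rep)))
  blue3 <- compute_blues(fit_blue_model(d3))
  expect_equal(blue3$blue, blue$blue, tolerance = 1e-8)
})

test_that("BLUPs shrink by the balanced-case closed-form factor", {
  set.seed(41)
  n_gen <- 40; n_rep <- 3
  d <- expand.grid(genotype = sprintf("G%02d", 1:n_gen), rep = factor(1:n_rep))
  g <- rnorm(n_gen, 0, 4)
  d$y <- 70 + g[as.integer(d$genotype)] + rnorm(nrow(d), 0, 2)
  fit <- fit_reml(d, "y", random = "genotype")
  s2g <- fit$sigma2[["genotype"]]; s2e <- fit$sigma2[["residual"]]
  gm <- tapply(d$y, d$genotype, mean)
  shrink <- s2g / (s2g + s2e / n_rep)
  want <- shrink * (gm - mean(gm))
  got <- fit$blup$genotype[names(gm)]
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-6)
  # centered by construction
  expect_lt(abs(sum(got)), 1e-6)
})

test_that("BLUP limiting behavior: full shrinkage and no shrinkage", {
  d <- expand.grid(genotype = sprintf("G%02d", 1:20), rep = factor(1:2))
  set.seed(3)
  # pure-noise response: genotype variance pinned at the boundary, BLUPs ~ 0
  d$y <- rnorm(nrow(d), 0, 3)
  fit0 <- fit_reml(d, "y", random = "genotype")
  if (fit0$sigma2[["genotype"]] == 0)
    expect_true(all(abs(fit0$blup$genotype) < 1e-6))
  # near-deterministic genotype differences: BLUPs ~ centered genotype means
  g <- seq(-20, 18, by = 2)
  d$y <- 70 + g[as.integer(d$genotype)] + rnorm(nrow(d), 0, 1e-3)
  fit1 <- fit_reml(d, "y", random = "genotype")
  gm <- tapply(d$y, d$genotype, mean)
  expect_equal(as.numeric(fit1$blup$genotype[names(gm)]),
               as.numeric(gm - mean(gm)), tolerance = 1e-3)
})

test_that("broad-sense heritability: formula arithmetic and degenerate limits", {
  vc <- c(genotype = 25, residual = 9)
  h <- broad_sense_heritability(vc, n_rep = 2)
  expect_equal(h$H2, 25 / (25 + 4.5), tolerance = 1e-12)
  expect_equal(broad_sense_heritability(c(genotype = 0, residual = 9), 2)$H2, 0)
  expect_equal(broad_sense_heritability(c(genotype = 25, residual = 0), 2)$H2, 1)
  expect_error(broad_sense_heritability(c(genotype = 0, residual = 0), 2),
               "undefined")
  vp <- c(genotype = 25, rep = 1, `rep:block` = 4, residual = 9)
  expect_equal(broad_sense_heritability(vp, 2, basis = "plot")$H2, 25 / 39)
})

test_that("heritability SE from the fitted information is finite and plausible", {
  d <- simulate_lattice_response(5, n_gen = 50, n_block = 10, sg = 5, sb = 2,
                                 se = 3)
  fit <- fit_reml(d, "ph_cm", random = c("genotype", "rep:block"), se = TRUE)
  vc <- fit$sigma2
  h <- broad_sense_heritability(
    structure(list(sigma2 = vc, vcov_sigma2 = fit$vcov_sigma2),
              class = "reml_fit"), n_rep = 2)
  expect_true(is.finite(h$se))
  expect_gt(h$se, 0)
  expect_lt(h$se, 0.5)
})

test_that("flight adjustment: identity for one flight, closed form for two balanced flights", {
  rec1 <- data.frame(plot_id = sprintf("P%02d", 1:6), flight = 1,
                     ph_cm = c(80, 85, 90, 95, 100, 105))
  out1 <- adjust_for_flights(rec1)
  expect_equal(out1$ph_cm, rec1$ph_cm)

  base <- c(80, 85, 90, 95)
  rec2 <- rbind(
    data.frame(plot_id = sprintf("P%02d", 1:4), flight = 1, ph_cm = base),
    data.frame(plot_id = sprintf("P%02d", 1:4), flight = 2, ph_cm = base + 2))
  out2 <- adjust_for_flights(rec2)
  expect_equal(out2$ph_cm, base + 1)  # per-plot mean over both flights
  # record order must not matter
  out2b <- adjust_for_flights(rec2[sample(nrow(rec2)), ])
  expect_equal(out2b, out2)
  # a plot absent from every flight is NA-flagged
  rec3 <- rbind(rec2, data.frame(plot_id = "P99", flight = 1, ph_cm = NA))
  out3 <- adjust_for_flights(rec3)
  expect_true(is.na(out3$ph_cm[out3$plot_id == "P99"]))
  expect_identical(out3$flag[out3$plot_id == "P99"], "missing_all_flights")
})

test_that("spearman: perfect monotone, reversed, hand-computed rho and p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_with_test(x, x^3)$rho, 1)
  expect_equal(spearman_with_test(x, rev(x))$rho, -1)
  # squared rank differences (1,1,1,1,0): rho = 1 - 6*4 / (5*24) = 0.8
  s <- spearman_with_test(x, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8)
  expect_equal(s$rho, cor(x, c(2, 1, 4, 3, 5), method = "spearman"))
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(s$p_value, 2 * pt(-tstat, 3))
  expect_error(spearman_with_test(x, rep(1, 5)), "constant")
  expect_error(spearman_with_test(1:2, 2:1), "at least 3")
  # the linear CI shortcut is what it says
  sl <- spearman_with_test(x, c(2, 1, 4, 3, 5), conf_method = "linear")
  expect_equal(sl$ci, 0.8 + c(-1, 1) * 1.96 * 0.2 / 3)
})
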