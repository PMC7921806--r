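# Genetic-selection statistics built on the REML engine: flight adjustment,
# BLUEs/BLUPs, heritabilities, the pedigree G x E model, and rank
# concordance.

#' Collapse repeated flights to a single value per plot
#'
#' When a growth stage was flown more than once, fits the additive two-way
#' fixed-effects model height ~ plot + flight and returns each plot's
#' adjusted mean (the plot's prediction averaged over all flight effects).
#' With a single flight the observed values pass through unchanged; plots
#' absent from every flight come back as NA with a flag.
#'
#' @param records data.frame with columns plot_id, flight, ph_cm (other
#'   columns are carried through from each plot's first record).
#' @return data.frame: one row per plot with adjusted ph_cm and flag.
#' @export
adjust_for_flights <- function(records) {
  stopifnot(all(c("plot_id", "flight", "ph_cm") %in% names(records)))
  records$plot_id <- as.character(records$plot_id)
  plots <- sort(unique(records$plot_id))
  carried <- records[!duplicated(records$plot_id), ]
  carried <- carried[match(plots, carried$plot_id),
                     setdiff(names(records), c("flight", "ph_cm")), drop = FALSE]
  flights <- unique(records$flight)
  complete <- records[!is.na(records$ph_cm), ]
  if (length(flights) == 1) {
    ph <- complete$ph_cm[match(plots, complete$plot_id)]
    out <- cbind(carried, ph_cm = ph,
                 flag = ifelse(is.na(ph), "missing_all_flights", "ok"))
    rownames(out) <- NULL
    return(out)
  }
  d <- data.frame(plot = factor(complete$plot_id, levels = plots),
                  flight = factor(complete$flight), y = complete$ph_cm)
  present <- levels(droplevels(d$plot))
  fit <- stats::lm(y ~ plot + flight, data = droplevels(d))
  grid <- expand.grid(plot = factor(present, levels = present),
                      flight = factor(levels(droplevels(d$flight))))
  pred <- suppressWarnings(stats::predict(fit, newdata = grid))
  adj <- tapply(pred, grid$plot, mean)
  ph <- as.numeric(adj[plots]); names(ph) <- NULL
  out <- cbind(carried, ph_cm = ph,
               flag = ifelse(is.na(ph), "missing_all_flights", "ok"))
  rownames(out) <- NULL
  out
}

#' Fit the BLUE model: genotype fixed, replicate and block random
#'
#' The per-plot model height = mu + genotype (fixed) + replicate (random) +
#' block within replicate (random) + residual, by REML.
#'
#' @param data data.frame with columns genotype, rep, block and the response.
#' @param response response column (default "ph_cm").
#' @param ... passed to \code{\link{fit_reml}}.
#' @return a \code{reml_fit}.
#' @export
fit_blue_model <- function(data, response = "ph_cm", ...) {
  fit_reml(data, response, fixed = "genotype", random = c("rep", "rep:block"), ...)
}

#' Fit the BLUP model: genotype random
#'
#' As \code{\link{fit_blue_model}} but with genotype as a random effect
#' (optionally with a relationship matrix), yielding shrunken genotype
#' predictions and the genotypic variance for heritability.
#'
#' @inheritParams fit_blue_model
#' @param relationship optional named list, e.g. \code{list(genotype = A)}.
#' @return a \code{reml_fit}.
#' @export
fit_blup_model <- function(data, response = "ph_cm", relationship = list(), ...) {
  fit_reml(data, response, fixed = NULL,
           random = c("genotype", "rep", "rep:block"),
           relationship = relationship, ...)
}

#' Genotype BLUEs from a genotype-fixed fit
#'
#' Best linear unbiased estimates: the estimable genotype means
#' (intercept + genotype effect under treatment coding; invariant to the
#' coding) with standard errors from the GLS covariance.
#'
#' @param fit a \code{reml_fit} with genotype among the fixed terms.
#' @return data.frame: genotype, blue (response units), se.
#' @export
compute_blues <- function(fit) {
  if (!"genotype" %in% names(fit$fixed_factors))
    stop("fit has no fixed genotype term; BLUEs require the genotype-fixed model")
  levs <- levels(fit$fixed_factors$genotype)
  cn <- names(fit$beta)
  est <- se <- numeric(length(levs))
  for (i in seq_along(levs)) {
    ctr <- stats::setNames(rep(0, length(cn)), cn)
    ctr["(Intercept)"] <- 1
    col <- paste0("genotype", levs[i])
    if (col %in% cn) ctr[col] <- 1  # reference level has no column
    est[i] <- sum(ctr * fit$beta)
    se[i] <- sqrt(drop(t(ctr) %*% fit$beta_vcov %*% ctr))
  }
  data.frame(genotype = levs, blue = est, se = se)
}

#' Genotype BLUPs from a genotype-random fit
#'
#' Shrunken genotype predictions from the mixed-model equations, with
#' prediction-error SEs; the vector is centered by construction.
#'
#' @param fit a \code{reml_fit} with "genotype" among the random terms.
#' @return data.frame: genotype, blup (deviation from the mean, response
#'   units), se.
#' @export
compute_blups <- function(fit) {
  if (!"genotype" %in% fit$random)
    stop("fit has no random genotype term; BLUPs require the genotype-random model")
  data.frame(genotype = names(fit$blup$genotype),
             blup = as.numeric(fit$blup$genotype),
             se = sqrt(as.numeric(fit$blup_pev$genotype)))
}

#' Broad-sense heritability (repeatability) from variance components
#'
#' Ratio of genotypic to total variance. Two denominators are offered because
#' "total variance" is convention-dependent: the entry-mean basis (default,
#' the repeatability of a genotype mean over \code{n_rep} replicates,
#' sigma2_g / (sigma2_g + sigma2_e / n_rep)) and the plot basis
#' (sigma2_g over the sum of all variance components). The SE is a
#' delta-method transform of the variance-component covariance when the fit
#' carries one.
#'
#' @param fit a \code{reml_fit} from the genotype-random model (or a named
#'   variance vector with elements "genotype" and "residual").
#' @param n_rep number of replicates (entry-mean basis only).
#' @param basis "entry_mean" or "plot".
#' @return list: H2, se (NA without a variance covariance), basis.
#' @export
broad_sense_heritability <- function(fit, n_rep, basis = c("entry_mean", "plot")) {
  basis <- match.arg(basis)
  vc <- if (inherits(fit, "reml_fit")) fit$sigma2 else fit
  if (!all(c("genotype", "residual") %in% names(vc)))
    stop("variance components must include 'genotype' and 'residual'")
  if (all(vc == 0)) stop("all variance components are zero; heritability undefined")
  g <- vc[["genotype"]]; e <- vc[["residual"]]
  denom <- switch(basis, entry_mean = g + e / n_rep, plot = sum(vc))
  H2 <- as.numeric(g / denom)

  se <- NA_real_
  V <- if (inherits(fit, "reml_fit")) fit$vcov_sigma2 else NULL
  if (!is.null(V) && all(is.finite(V))) {
    grad <- stats::setNames(rep(0, length(vc)), names(vc))
    if (basis == "entry_mean") {
      grad["genotype"] <- (denom - g) / denom^2
      grad["residual"] <- -g / (n_rep * denom^2)
    } else {
      grad[] <- -g / denom^2
      grad["genotype"] <- (denom - g) / denom^2
    }
    grad <- grad[rownames(V)]
    se <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  list(H2 = H2, se = se, basis = basis)
}

#' Genotype-by-year (G x E) model with a pedigree relationship matrix
#'
#' REML fit over two (or more) crop cycles: fixed year means; random additive
#' genotype effects correlated by the A-matrix (N(0, A sigma2_a)), an
#' independent genotype-by-year interaction, and replicates and blocks nested
#' in year. Narrow-sense heritability uses the additive variance: entry-mean
#' basis sigma2_a / (sigma2_a + sigma2_ge / n_year + sigma2_e /
#' (n_year * n_rep)), or the plot basis over the sum of all components.
#'
#' @param data data.frame with columns genotype, year, rep, block and the
#'   response; at least two years.
#' @param A additive relationship matrix covering the genotypes (identity
#'   reduces to independent genotype effects).
#' @param response response column.
#' @param ... passed to \code{\link{fit_reml}}.
#' @return list of class \code{gxe_fit}: fit (reml_fit), sigma2 (named with
#'   additive, gxe, rep, block, residual), h2a_entry_mean, h2a_plot, blup
#'   (additive genotype predictions).
#' @export
fit_gxe <- function(data, A, response = "ph_cm", ...) {
  stopifnot(all(c("genotype", "year", "rep", "block") %in% names(data)))
  years <- unique(data$year[!is.na(data$year)])
  if (length(years) < 2)
    stop("G x E interaction is inestimable from a single year of data")
  fit <- fit_reml(data, response, fixed = "year",
                  random = c("genotype", "genotype:year", "year:rep",
                             "year:rep:block"),
                  relationship = list(genotype = A), ...)
  vc <- fit$sigma2
  n_year <- length(years)
  n_rep <- length(unique(data$rep[!is.na(data$rep)]))
  a <- vc[["genotype"]]; ge <- vc[["genotype:year"]]; e <- vc[["residual"]]
  h2a_em <- a / (a + ge / n_year + e / (n_year * n_rep))
  h2a_plot <- a / sum(vc)
  structure(list(fit = fit,
                 sigma2 = stats::setNames(vc, c("additive", "gxe", "rep",
                                                "block", "residual")),
                 h2a_entry_mean = as.numeric(h2a_em),
                 h2a_plot = as.numeric(h2a_plot),
                 blup = data.frame(genotype = names(fit$blup$genotype),
                                   blup = as.numeric(fit$blup$genotype))),
            class = "gxe_fit")
}

#' Spearman rank correlation with significance test
#'
#' rho on average ranks; the p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom. The
#' confidence interval uses the Fisher z transform by default; the
#' \code{"linear"} method instead uses the half-width 1.96 (1 - rho) /
#' (n - 2), a shortcut sometimes printed alongside prediction-accuracy plots
#' (kept for comparability; its width does not scale like a sampling SE).
#'
#' @param x,y paired numeric vectors (pairs with NA are dropped), n >= 3.
#' @param conf_method "fisher" or "linear".
#' @return list: rho, p_value, n, ci (length 2), conf_method.
#' @export
spearman_with_test <- function(x, y, conf_method = c("fisher", "linear")) {
  conf_method <- match.arg(conf_method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman test needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector; rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  ci <- if (conf_method == "fisher") {
    if (abs(rho) >= 1) c(rho, rho) else {
      z <- atanh(rho); hw <- 1.96 / sqrt(n - 3)
      tanh(c(z - hw, z + hw))
    }
  } else {
    hw <- 1.96 * (1 - rho) / (n - 2)
    c(rho - hw, rho + hw)
  }
  list(rho = rho, p_value = p, n = n, ci = ci, conf_method = conf_method)
}
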