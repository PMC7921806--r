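# REML estimation of variance components for the trial's mixed models via
# Henderson's mixed-model equations: EM updates (monotone in the restricted
# likelihood) with Aitken acceleration. Correlated random effects (pedigree
# A-matrix) reduce to the independent-effects machinery through the Cholesky
# factor of the relationship matrix.

# Build design matrices. `term` is a column name or a ":"-interaction of
# column names; every term is treated as a factor grouping.
term_factor <- function(data, term) {
  cols <- strsplit(term, ":", fixed = TRUE)[[1]]
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("term '", term, "': columns not in data: ",
                            paste(missing, collapse = ", "))
  interaction(data[cols], drop = TRUE, sep = ":", lex.order = TRUE)
}

incidence <- function(f) {
  Z <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' Fit a mixed model by REML
#'
#' Estimates variance components by restricted maximum likelihood using EM
#' steps on the mixed-model equations (each step cannot decrease the
#' restricted log-likelihood), accelerated by Aitken extrapolation; fixed
#' effects are generalized-least-squares solutions at the estimates and
#' random effects are BLUPs from the same equations. Variances are
#' constrained non-negative; an estimate pinned at (effectively) zero is
#' flagged as a boundary solution.
#'
#' @param data data.frame holding the response and all grouping columns.
#' @param response name of the numeric response column.
#' @param fixed character vector of fixed-effect terms (factors), besides the
#'   intercept; e.g. \code{"genotype"} for a BLUE model. NULL = intercept only.
#' @param random character vector of random-effect grouping terms; an
#'   interaction is written \code{"rep:block"}.
#' @param relationship named list mapping a random term to a relationship
#'   (covariance-structure) matrix with dimnames covering the term's levels;
#'   effects for that term are distributed N(0, K sigma2). A ridge of 1e-8 is
#'   added if the Cholesky factorization fails.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   trace.
#' @param se if TRUE, the asymptotic covariance of the variance components is
#'   computed from the numerically differentiated restricted log-likelihood.
#' @return object of class \code{reml_fit}: \code{sigma2} (named vector,
#'   random terms then \code{residual}), \code{beta} and \code{beta_vcov},
#'   \code{blup} (named list, original scale), \code{blup_pev} (prediction
#'   error variances), \code{loglik} (restricted), \code{vcov_sigma2},
#'   \code{convergence} (iterations, converged, boundary flags, trace), and
#'   the model frame metadata.
#' @export
fit_reml <- function(data, response, fixed = NULL, random,
                     relationship = list(), tol = 1e-8, max_iter = 2000L,
                     se = FALSE) {
  stopifnot(response %in% names(data), length(random) >= 1)
  keep <- !is.na(data[[response]])
  for (tm in c(fixed, random))
    for (col in strsplit(tm, ":", fixed = TRUE)[[1]])
      keep <- keep & !is.na(data[[col]])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[response]])
  n <- length(y)

  # fixed design with intercept, treatment coding
  if (is.null(fixed)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    fixed_factors <- list()
  } else {
    fixed_factors <- lapply(fixed, function(tm) term_factor(data, tm))
    names(fixed_factors) <- fixed
    fml <- stats::as.formula(paste("~", paste(sprintf("f%d", seq_along(fixed)),
                                              collapse = " + ")))
    env <- as.data.frame(stats::setNames(fixed_factors,
                                         sprintf("f%d", seq_along(fixed))))
    X <- stats::model.matrix(fml, env)
    # restore readable column names
    for (i in seq_along(fixed))
      colnames(X) <- sub(sprintf("^f%d", i), fixed[i], colnames(X))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect parameters")

  # random designs; correlated terms absorbed via the Cholesky factor
  rf <- lapply(random, function(tm) term_factor(data, tm))
  names(rf) <- random
  Zs <- list(); Ls <- list()
  for (tm in random) {
    Z <- incidence(rf[[tm]])
    L <- NULL
    if (tm %in% names(relationship)) {
      K <- relationship[[tm]]
      lev <- levels(rf[[tm]])
      if (!all(lev %in% rownames(K)))
        stop("relationship matrix for '", tm, "' misses levels: ",
             paste(setdiff(lev, rownames(K)), collapse = ", "))
      K <- K[lev, lev]
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) {
        ch <- tryCatch(chol(K + diag(1e-8, nrow(K))), error = function(e) NULL)
        if (is.null(ch)) stop("relationship matrix for '", tm,
                              "' is not positive semidefinite (even with ridge 1e-8)")
      }
      L <- t(ch)
      Z <- Z %*% L  # u = L a with a iid, so the working design is Z L
    }
    Zs[[tm]] <- Z; Ls[[tm]] <- L
  }

  q_k <- vapply(Zs, ncol, integer(1))
  Z <- do.call(cbind, Zs)
  q <- sum(q_k)
  blocks <- split(seq_len(q), rep(seq_along(q_k), q_k))

  W <- cbind(X, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  yty <- sum(y^2)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-20) {
    sigma2 <- stats::setNames(rep(0, length(random) + 1), c(random, "residual"))
    beta <- qr.coef(qrX, y)
    return(structure(list(
      sigma2 = sigma2, beta = beta,
      beta_vcov = matrix(0, p, p, dimnames = list(colnames(X), colnames(X))),
      blup = lapply(stats::setNames(random, random),
                    function(tm) stats::setNames(rep(0, nlevels(rf[[tm]])),
                                                 levels(rf[[tm]]))),
      blup_pev = NULL, loglik = NA_real_, vcov_sigma2 = NULL,
      convergence = list(iterations = 0L, converged = TRUE,
                         boundary = stats::setNames(rep(TRUE, length(random) + 1),
                                                    c(random, "residual"))),
      n = n, p = p, q_k = q_k, random = random, fixed = fixed,
      levels = lapply(rf, levels), L = Ls, response = response),
      class = "reml_fit"))
  }
  floor_v <- 1e-10 * vy

  mme_solve <- function(s2, s2e) {
    C <- WtW
    for (k in seq_along(blocks)) {
      idx <- p + blocks[[k]]
      diag(C)[idx] <- diag(C)[idx] + s2e / s2[k]
    }
    ch <- chol(C)
    sol <- backsolve(ch, forwardsolve(t(ch), Wty))
    list(ch = ch, sol = sol)
  }

  reml_m2ll <- function(s2, s2e, ms = NULL) {
    if (is.null(ms)) ms <- mme_solve(s2, s2e)
    ypy <- (yty - sum(ms$sol * Wty)) / s2e
    (n - p - q) * log(s2e) + sum(q_k * log(s2)) +
      2 * sum(log(diag(ms$ch))) + ypy
  }

  s2 <- rep(vy / (length(random) + 1), length(random))
  s2e <- vy / (length(random) + 1)
  trace <- matrix(NA_real_, 0, length(random) + 1)
  hist_par <- list()
  converged <- FALSE
  m2ll_prev <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ms <- mme_solve(s2, s2e)
    m2ll_cur <- reml_m2ll(s2, s2e, ms)
    Cinv <- chol2inv(ms$ch)
    sol <- ms$sol
    s2_new <- s2
    for (k in seq_along(blocks)) {
      idx <- p + blocks[[k]]
      uk <- sol[idx]
      s2_new[k] <- max(floor_v,
                       (sum(uk^2) + s2e * sum(diag(Cinv)[idx])) / q_k[k])
    }
    s2e_new <- max(floor_v, (yty - sum(sol * Wty)) / (n - p))
    par_old <- c(s2, s2e); par_new <- c(s2_new, s2e_new)
    trace <- rbind(trace, par_new)
    hist_par[[length(hist_par) + 1]] <- par_new

    # Aitken extrapolation on each component every third iteration
    if (length(hist_par) >= 3 && it %% 3 == 0) {
      h <- length(hist_par)
      t1 <- hist_par[[h - 2]]; t2 <- hist_par[[h - 1]]; t3 <- hist_par[[h]]
      denom <- (t3 - t2) - (t2 - t1)
      acc <- ifelse(abs(denom) > 1e-300, t3 - (t3 - t2)^2 / denom, t3)
      acc <- pmax(acc, floor_v)
      if (all(is.finite(acc))) {
        cur <- reml_m2ll(par_new[seq_along(s2)], par_new[length(par_new)])
        prop <- reml_m2ll(acc[seq_along(s2)], acc[length(acc)])
        if (prop <= cur) { par_new <- acc; hist_par <- list() }
      }
    }
    s2 <- par_new[seq_along(s2)]; s2e <- par_new[length(par_new)]
    # stop on parameter stability, or on a stationary restricted likelihood
    # (the parameter path can jitter at numerical-noise level when a variance
    # is pinned at the zero boundary and the equations grow ill-conditioned)
    if (max(abs(par_new - par_old) / pmax(abs(par_old), floor_v)) < tol ||
        (it > 10 && abs(m2ll_cur - m2ll_prev) < 1e-9 * (1 + abs(m2ll_cur)))) {
      converged <- TRUE
      break
    }
    m2ll_prev <- m2ll_cur
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "REML did not converge in %d iterations (last relative change above %g)",
      max_iter, tol))
    err$trace <- trace
    stop(err)
  }

  ms <- mme_solve(s2, s2e)
  Cinv <- chol2inv(ms$ch)
  sol <- ms$sol
  beta <- stats::setNames(sol[seq_len(p)], colnames(X))
  beta_vcov <- s2e * Cinv[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(beta_vcov) <- list(colnames(X), colnames(X))

  blup <- list(); blup_pev <- list()
  for (k in seq_along(random)) {
    tm <- random[k]
    idx <- p + blocks[[k]]
    a <- sol[idx]
    pev <- s2e * Cinv[idx, idx, drop = FALSE]
    if (!is.null(Ls[[tm]])) {     # back to the correlated scale u = L a
      a <- as.vector(Ls[[tm]] %*% a)
      pev <- Ls[[tm]] %*% pev %*% t(Ls[[tm]])
    }
    blup[[tm]] <- stats::setNames(a, levels(rf[[tm]]))
    blup_pev[[tm]] <- stats::setNames(diag(pev), levels(rf[[tm]]))
  }

  sigma2 <- stats::setNames(c(s2, s2e), c(random, "residual"))
  boundary <- sigma2 <= floor_v * (1 + 1e-6)
  sigma2[boundary] <- 0
  loglik <- -0.5 * (reml_m2ll(pmax(s2, floor_v), max(s2e, floor_v)) +
                      (n - p) * log(2 * pi))

  vcov_sigma2 <- NULL
  if (se) vcov_sigma2 <- reml_vcov_numeric(reml_m2ll, s2, s2e, floor_v,
                                           c(random, "residual"))

  structure(list(sigma2 = sigma2, beta = beta, beta_vcov = beta_vcov,
                 blup = blup, blup_pev = blup_pev, loglik = loglik,
                 vcov_sigma2 = vcov_sigma2,
                 convergence = list(iterations = it, converged = converged,
                                    boundary = stats::setNames(boundary,
                                                               c(random, "residual")),
                                    trace = trace),
                 n = n, p = p, q_k = q_k, random = random, fixed = fixed,
                 fixed_factors = fixed_factors,
                 levels = lapply(rf, levels), L = Ls, response = response,
                 m2ll_fun = reml_m2ll),
            class = "reml_fit")
}

# asymptotic covariance of variance-component estimates: inverse of the
# observed information from a central-difference Hessian of the restricted
# log-likelihood (in -2ll units, information = Hessian / 2)
reml_vcov_numeric <- function(m2ll, s2, s2e, floor_v, nm) {
  th <- c(s2, s2e)
  k <- length(th)
  f <- function(t) m2ll(pmax(t[-k], floor_v), max(t[k], floor_v))
  h <- pmax(abs(th) * 1e-4, floor_v)
  H <- matrix(NA_real_, k, k)
  f0 <- f(th)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- rep(0, k); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(th + ei) - 2 * f0 + f(th - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) + f(th - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  V <- tryCatch(solve(H / 2), error = function(e) matrix(NA_real_, k, k))
  dimnames(V) <- list(nm, nm)
  V
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the model's restricted log-likelihood at arbitrary admissible
#' variances, e.g. to audit that the REML optimum dominates random parameter
#' points.
#'
#' @param fit a \code{reml_fit}.
#' @param sigma2 named or positional vector of variances in the order
#'   \code{c(fit$random, "residual")}, all > 0.
#' @return restricted log-likelihood (including the Gaussian constant).
#' @export
reml_loglik_at <- function(fit, sigma2) {
  stopifnot(length(sigma2) == length(fit$random) + 1, all(sigma2 > 0))
  k <- length(sigma2)
  -0.5 * (fit$m2ll_fun(sigma2[-k], sigma2[k]) + (fit$n - fit$p) * log(2 * pi))
}
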