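## Marker-effect estimation.
##
## Three methods share one contract: given a training dosage matrix X
## (individuals x markers) and phenotypes y they return an
## `effect_estimate` holding per-marker additive effects and the training
## column means; breeding values of new individuals are the centered
## genotypes times the effects (no intercept: breeding values are
## deviations).

new_effect_estimate <- function(method, effects, center, intercept,
                                diagnostics = list()) {
  structure(list(method = method, effects = as.numeric(effects),
                 center = as.numeric(center), intercept = intercept,
                 diagnostics = diagnostics),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  nz <- sum(abs(x$effects) > 1e-12)
  cat(sprintf("effect_estimate [%s]: %d markers (%d nonzero)\n",
              x$method, length(x$effects), nz))
  invisible(x)
}

#' Marker-estimated breeding values
#'
#' MEBV = (X - training column means) a.  Predictions are centered
#' deviations; set \code{include_intercept = TRUE} to add the training
#' phenotype mean for raw-scale predictions.
#'
#' @param X_new genotype dosage matrix of the individuals to predict.
#' @param estimate an \code{effect_estimate}.
#' @param include_intercept add the stored intercept.
#' @return numeric vector of MEBV.
#' @export
predict_mebv <- function(X_new, estimate, include_intercept = FALSE) {
  if (ncol(X_new) != length(estimate$effects))
    stop("column count of X_new does not match the effect vector")
  mebv <- drop(sweep(X_new, 2L, estimate$center) %*% estimate$effects)
  if (include_intercept) mebv <- mebv + estimate$intercept
  mebv
}

#' Configuration of the Bayesian mixture sampler
#'
#' Priors: each marker is associated with a QTL with probability
#' \code{prior_n_qtl / M}; associated markers draw their effect from
#' N(0, \code{prior_qtl_variance}), the rest from the same normal scaled
#' down by \code{small_variance_ratio} (default 1/100).  The QTL variance
#' prior is interpreted on a standardized-phenotype scale (the phenotype
#' is scaled to unit variance before sampling and effects are rescaled on
#' output), since raw phenotypic variances vary over orders of magnitude
#' across QTL architectures.
#'
#' @param prior_n_qtl prior number of markers associated with QTL.
#' @param prior_qtl_variance prior effect variance of associated markers
#'   (standardized-phenotype scale).
#' @param small_variance_ratio ratio of the non-associated to the
#'   associated effect variance.
#' @param n_iter Gibbs chain length.
#' @param burn_in iterations discarded before averaging.
#' @param variance_model \code{"fixed"} (two fixed mixture variances, the
#'   default) or \code{"marker"} (per-marker QTL variances with a scaled
#'   inverse-chi-square prior of mean \code{prior_qtl_variance} and
#'   \code{nu0} degrees of freedom, updated jointly with the indicator by
#'   Metropolis-Hastings proposals from the prior).
#' @param nu0 prior degrees of freedom of the per-marker variance
#'   (\code{variance_model = "marker"} only).
#' @return object of class \code{bm_config}.
#' @export
bm_config <- function(prior_n_qtl = 50L, prior_qtl_variance = 0.20,
                      small_variance_ratio = 1 / 100,
                      n_iter = 10000L, burn_in = 1000L,
                      variance_model = c("fixed", "marker"), nu0 = 4.012) {
  variance_model <- match.arg(variance_model)
  stopifnot(prior_n_qtl >= 1L, prior_qtl_variance > 0,
            small_variance_ratio > 0, small_variance_ratio <= 1,
            burn_in < n_iter, nu0 > 2)
  structure(list(prior_n_qtl = as.integer(prior_n_qtl),
                 prior_qtl_variance = prior_qtl_variance,
                 small_variance_ratio = small_variance_ratio,
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 variance_model = variance_model, nu0 = nu0),
            class = "bm_config")
}

#' Fit the Bayesian mixture model by Gibbs sampling
#'
#' Model: y = mu + X a + e with per-marker indicators delta_j ~
#' Bernoulli(pi), a_j | delta_j ~ N(0, v1) or N(0, v1/100), e ~
#' N(0, sigma2e I).  Indicators are sampled from the two-component
#' marginal with the effect integrated out; effects and the intercept
#' from their normal full conditionals; sigma2e from its scaled
#' inverse-chi-square full conditional under a flat prior.  Reported
#' effects are posterior means over the post-burn-in iterations.
#'
#' @param X training dosage matrix (n x M).
#' @param y training phenotypes.
#' @param config a [bm_config()].
#' @param seed optional seed for the chain.
#' @return an \code{effect_estimate} with diagnostics
#'   \code{inclusion_prob} (posterior inclusion probability per marker)
#'   and \code{sigma2e_trace}.
#' @export
fit_bm <- function(X, y, config = bm_config(), seed = NULL) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 3L, ncol(X) >= 1L)
  if (any(!is.finite(y))) stop("non-finite phenotypes")
  ysd <- sd(y)
  if (!(ysd > 0)) stop("phenotypes have zero variance")
  if (!is.null(seed)) set.seed(seed)
  ybar <- mean(y)
  ys <- (y - ybar) / ysd
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  M <- ncol(X)
  pi1 <- min(config$prior_n_qtl / M, 0.999)
  v1 <- config$prior_qtl_variance
  v2 <- v1 * config$small_variance_ratio
  fit <- if (identical(config$variance_model, "marker"))
    bm_gibbs_mh_cpp(Xc, ys, pi1, v1, v2, config$nu0, 10L,
                    config$n_iter, config$burn_in)
  else
    bm_gibbs_cpp(Xc, ys, pi1, v1, v2, config$n_iter, config$burn_in)
  new_effect_estimate(
    "BM", fit$effects * ysd, ctr, intercept = ybar,
    diagnostics = list(inclusion_prob = as.numeric(fit$inclusion_prob),
                       sigma2e_trace = as.numeric(fit$sigma2e_trace) * ysd^2,
                       pi = pi1, config = config))
}

## ---------------------------------------------------------------- LARS --

#' Least angle regression path
#'
#' Computes the LARS coefficient path on centered (and by default
#' unit-norm scaled) predictors: starting from the zero model, the
#' predictor most correlated with the residual joins the active set and
#' the coefficients move in the equiangular direction until another
#' predictor reaches the same absolute correlation.  After k steps the
#' model holds k predictors.  The Gram factor is maintained by Cholesky
#' updates; an exactly collinear entrant is skipped with a warning.  With
#' \code{lasso = TRUE} the lasso modification applies (a coefficient
#' whose sign would change is dropped at the crossing).
#'
#' @param X predictor matrix.
#' @param y response.
#' @param max_steps maximum number of steps (default min(n - 1, M)).
#' @param normalize scale predictors to unit L2 norm internally.
#' @param lasso use the lasso modification.
#' @return list with \code{beta} (one row per step, including the zero
#'   step, on the original predictor scale), \code{active} (entry order)
#'   and \code{n_steps}.
#' @export
lars_path <- function(X, y, max_steps = NULL, normalize = TRUE,
                      lasso = FALSE) {
  n <- nrow(X); M <- ncol(X)
  stopifnot(length(y) == n, n >= 2L)
  eps <- 1e-10
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  scl <- if (normalize) sqrt(colSums(Xc^2)) else rep(1, M)
  usable <- scl > eps
  scl[!usable] <- 1
  Xs <- sweep(Xc, 2L, scl, "/")
  yc <- y - mean(y)
  if (is.null(max_steps)) max_steps <- min(n - 1L, sum(usable))
  max_steps <- min(max_steps, sum(usable))

  cvec <- drop(crossprod(Xs, yc))
  active <- integer(0)
  signs <- numeric(0)
  Rchol <- matrix(0, 0, 0)          # upper Cholesky of Gram of active set
  beta <- numeric(M)
  beta_steps <- matrix(0, nrow = max_steps + 1L, ncol = M)
  excluded <- !usable
  step <- 0L
  skipped <- integer(0)

  while (step < max_steps) {
    inactive <- which(!excluded & !(seq_len(M) %in% active))
    if (!length(inactive) && !lasso) break
    if (length(inactive)) {
      Cmax_in <- max(abs(cvec[inactive]))
    } else Cmax_in <- -Inf
    if (!length(active) || Cmax_in >= max(abs(cvec[active])) - eps) {
      if (!length(inactive) || Cmax_in < eps) break
      j_new <- inactive[which.max(abs(cvec[inactive]))]
      # Cholesky update with column j_new
      xj <- Xs[, j_new]
      if (!length(active)) {
        d2 <- sum(xj^2)
        if (d2 < eps) { excluded[j_new] <- TRUE; next }
        Rchol <- matrix(sqrt(d2), 1L, 1L)
        active <- j_new
        signs <- sign(cvec[j_new])
      } else {
        g <- drop(crossprod(Xs[, active, drop = FALSE], xj))
        rvec <- backsolve(Rchol, g, transpose = TRUE)
        d2 <- sum(xj^2) - sum(rvec^2)
        if (d2 < eps) {
          skipped <- c(skipped, j_new)
          excluded[j_new] <- TRUE
          next
        }
        k <- length(active)
        Rnew <- matrix(0, k + 1L, k + 1L)
        Rnew[seq_len(k), seq_len(k)] <- Rchol
        Rnew[seq_len(k), k + 1L] <- rvec
        Rnew[k + 1L, k + 1L] <- sqrt(d2)
        Rchol <- Rnew
        active <- c(active, j_new)
        signs <- c(signs, sign(cvec[j_new]))
      }
    }

    Cmax <- max(abs(cvec[active]))
    # equiangular direction: d = A * G^-1 s in coefficient space
    s <- signs
    Ginv_s <- backsolve(Rchol, backsolve(Rchol, s, transpose = TRUE))
    Anorm <- 1 / sqrt(sum(s * Ginv_s))
    d <- Anorm * Ginv_s
    u <- drop(Xs[, active, drop = FALSE] %*% d)   # unit equiangular vector
    a <- drop(crossprod(Xs, u))

    inactive <- which(!excluded & !(seq_len(M) %in% active))
    if (length(inactive)) {
      gam1 <- (Cmax - cvec[inactive]) / (Anorm - a[inactive])
      gam2 <- (Cmax + cvec[inactive]) / (Anorm + a[inactive])
      cand <- c(gam1, gam2)
      cand <- cand[is.finite(cand) & cand > eps]
      gamma <- if (length(cand)) min(cand) else Cmax / Anorm
    } else {
      gamma <- Cmax / Anorm
    }
    gamma <- min(gamma, Cmax / Anorm)

    dropped <- FALSE
    if (lasso) {
      gam_drop <- -beta[active] / d
      gam_drop[!is.finite(gam_drop) | gam_drop <= eps] <- Inf
      if (min(gam_drop) < gamma) {
        gamma <- min(gam_drop)
        drop_j <- which.min(gam_drop)
        dropped <- TRUE
      }
    }

    beta[active] <- beta[active] + gamma * d
    cvec <- cvec - gamma * a

    if (dropped) {
      beta[active[drop_j]] <- 0
      keep <- setdiff(seq_along(active), drop_j)
      active <- active[keep]
      signs <- signs[keep]
      Rchol <- if (length(active))
        chol(crossprod(Xs[, active, drop = FALSE])) else matrix(0, 0, 0)
    } else {
      step <- step + 1L
      beta_steps[step + 1L, ] <- beta / scl
    }
    if (max(abs(cvec)) < eps) break
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " exactly collinear predictor(s)")
  used <- step
  list(beta = beta_steps[seq_len(used + 1L), , drop = FALSE],
       active = active, n_steps = used, center = ctr)
}

cv_folds_assign <- function(n, k) sample(rep(seq_len(k), length.out = n))

#' Fit marker effects by LARS with cross-validated step selection
#'
#' Computes the LARS path, selects the step (number of markers in the
#' model) minimizing the k-fold cross-validation mean squared prediction
#' error on the training data (plain minimum; smallest step on ties),
#' and returns the full-data coefficients at that step.
#'
#' @param X training dosage matrix.
#' @param y training phenotypes.
#' @param cv_folds number of folds.
#' @param max_steps optional cap on path length.
#' @param lasso use the lasso modification of LARS.
#' @param seed optional seed controlling fold assignment.
#' @return an \code{effect_estimate} with diagnostics \code{step} and
#'   \code{cv_error} (mean CV error per step, starting at step 0).
#' @export
fit_lars <- function(X, y, cv_folds = 10L, max_steps = NULL, lasso = FALSE,
                     seed = NULL) {
  n <- nrow(X)
  stopifnot(length(y) == n, cv_folds >= 2L, n >= cv_folds)
  if (!is.null(seed)) set.seed(seed)
  folds <- cv_folds_assign(n, cv_folds)
  if (is.null(max_steps)) max_steps <- min(n - 1L, ncol(X))
  n_eval <- max_steps
  sse <- matrix(NA_real_, nrow = cv_folds, ncol = n_eval + 1L)
  cnt <- integer(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    path <- lars_path(X[tr, , drop = FALSE], y[tr],
                      max_steps = max_steps, lasso = lasso)
    Xv <- sweep(X[!tr, , drop = FALSE], 2L, path$center)
    mu_tr <- mean(y[tr])
    pred <- Xv %*% t(path$beta) + mu_tr     # n_val x (steps+1)
    err <- colSums((y[!tr] - pred)^2)
    ks <- seq_len(min(path$n_steps, n_eval) + 1L)
    sse[f, ks] <- err[ks]
    # fold paths shorter than the grid: carry the last model forward
    if (length(ks) <= n_eval)
      sse[f, (length(ks) + 1L):(n_eval + 1L)] <- err[length(ks)]
    cnt[f] <- sum(!tr)
  }
  cv_err <- colSums(sse) / n
  best <- which.min(cv_err) - 1L           # step index (0 = null model)
  full <- lars_path(X, y, max_steps = max_steps, lasso = lasso)
  step_use <- min(best, full$n_steps)
  new_effect_estimate(
    "LARS", full$beta[step_use + 1L, ], full$center, intercept = mean(y),
    diagnostics = list(step = step_use, cv_error = cv_err,
                       active = full$active, lasso = lasso))
}

## ---------------------------------------------------------------- PLSR --

#' Univariate partial least squares fit (PLS1)
#'
#' NIPALS-equivalent deflation scheme: each component is an orthogonal
#' score vector built from a weight vector proportional to the covariance
#' of the deflated predictors with the response.  Stops early when the
#' residual predictor or response structure is numerically exhausted.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param ncomp number of components requested.
#' @return list with \code{W}, \code{P}, \code{q}, \code{scores},
#'   \code{ncomp} (components actually fitted), \code{center},
#'   \code{y_mean} and \code{coef(k)} accessible via
#'   [pls1_coefficients()].
#' @export
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X); M <- ncol(X)
  stopifnot(length(y) == n)
  ncomp <- min(ncomp, n, M)
  ctr <- colMeans(X)
  Xr <- sweep(X, 2L, ctr)
  ybar <- mean(y)
  yc <- y - ybar
  W <- matrix(0, M, ncomp); P <- matrix(0, M, ncomp)
  qv <- numeric(ncomp); Tm <- matrix(0, n, ncomp)
  eps <- 1e-12
  scale0 <- max(sum(Xr^2), eps)
  k <- 0L
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xr, yc))
    nw <- sqrt(sum(w^2))
    if (nw < eps * sqrt(scale0)) break
    w <- w / nw
    tvec <- drop(Xr %*% w)
    tt <- sum(tvec^2)
    if (tt < eps * scale0) break
    p <- drop(crossprod(Xr, tvec)) / tt
    qh <- sum(yc * tvec) / tt
    Xr <- Xr - tcrossprod(tvec, p)
    yc <- yc - qh * tvec
    k <- h
    W[, h] <- w; P[, h] <- p; qv[h] <- qh; Tm[, h] <- tvec
  }
  list(W = W[, seq_len(k), drop = FALSE], P = P[, seq_len(k), drop = FALSE],
       q = qv[seq_len(k)], scores = Tm[, seq_len(k), drop = FALSE],
       ncomp = k, center = ctr, y_mean = ybar)
}

#' Collapsed regression coefficients of a PLS1 fit
#'
#' @param fit output of [pls1_fit()].
#' @param k number of components to use (up to \code{fit$ncomp}).
#' @return per-predictor coefficient vector.
#' @export
pls1_coefficients <- function(fit, k = fit$ncomp) {
  k <- min(k, fit$ncomp)
  if (k == 0L) return(numeric(nrow(fit$W)))
  Wk <- fit$W[, seq_len(k), drop = FALSE]
  Pk <- fit$P[, seq_len(k), drop = FALSE]
  drop(Wk %*% solve(crossprod(Pk, Wk), fit$q[seq_len(k)]))
}

#' Fit marker effects by PLSR with an iterative component search
#'
#' Cross-validation over component counts with a growing ceiling: a model
#' with 10 components is fitted and the CV-optimal count in 1..10 found;
#' if the optimum equals the ceiling, the ceiling is raised by 10 and the
#' search repeated, until the optimum falls below the ceiling or the
#' ceiling reaches min(n, M).  The returned effects are the collapsed
#' per-marker regression vector at the chosen component count.
#'
#' @param X training dosage matrix.
#' @param y training phenotypes.
#' @param block ceiling increment (10 in the standard protocol).
#' @param cv_folds number of folds.
#' @param seed optional seed controlling fold assignment.
#' @return an \code{effect_estimate} with diagnostics \code{ncomp} and
#'   \code{cv_error}.
#' @export
fit_plsr <- function(X, y, block = 10L, cv_folds = 10L, seed = NULL) {
  n <- nrow(X)
  stopifnot(length(y) == n, cv_folds >= 2L, n >= cv_folds)
  if (!is.null(seed)) set.seed(seed)
  folds <- cv_folds_assign(n, cv_folds)
  cap <- min(n, ncol(X))
  ceiling_k <- min(block, cap)
  repeat {
    sse <- matrix(0, nrow = cv_folds, ncol = ceiling_k + 1L)
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], ncomp = ceiling_k)
      Xv <- sweep(X[!tr, , drop = FALSE], 2L, fit$center)
      yv <- y[!tr]
      for (k in 0:ceiling_k) {
        bk <- pls1_coefficients(fit, k)
        pred <- drop(Xv %*% bk) + fit$y_mean
        sse[f, k + 1L] <- sum((yv - pred)^2)
      }
    }
    cv_err <- colSums(sse) / n
    best <- which.min(cv_err[-1L])          # components 1..ceiling
    if (best < ceiling_k || ceiling_k >= cap) break
    ceiling_k <- min(ceiling_k + block, cap)
  }
  full <- pls1_fit(X, y, ncomp = best)
  k_use <- min(best, full$ncomp)
  new_effect_estimate(
    "PLSR", pls1_coefficients(full, k_use), full$center,
    intercept = full$y_mean,
    diagnostics = list(ncomp = k_use, cv_error = cv_err,
                       ceiling = ceiling_k))
}

#' Fit marker effects with a chosen method
#'
#' Thin dispatcher over [fit_bm()], [fit_lars()] and [fit_plsr()].
#'
#' @param method "BM", "LARS" or "PLSR".
#' @param X training dosage matrix.
#' @param y training phenotypes.
#' @param seed optional seed.
#' @param ... passed to the method function.
#' @return an \code{effect_estimate}.
#' @export
fit_effects <- function(method = c("BM", "LARS", "PLSR"), X, y,
                        seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         BM = fit_bm(X, y, seed = seed, ...),
         LARS = fit_lars(X, y, seed = seed, ...),
         PLSR = fit_plsr(X, y, seed = seed, ...))
}
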