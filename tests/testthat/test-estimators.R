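# Oracles: closed-form least squares and soft-thresholding on orthogonal
# designs, lm() fits, and Monte-Carlo calibration of the Gibbs sampler.

make_regression_toy <- function(n, M, beta, sd_e = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * M), n, M)
  y <- drop(X %*% beta) + rnorm(n, 0, sd_e)
  list(X = X, y = y)
}

## ------------------------------------------------------------------ BM --

test_that("BM recovers a strong single-marker association", {
  set.seed(21)
  x <- rbinom(50, 2, 0.5)
  y <- 1.2 * x + rnorm(50, 0, 0.5)
  X <- cbind(x)
  est <- fit_bm(X, y, bm_config(prior_n_qtl = 1L, prior_qtl_variance = 0.5,
                                n_iter = 4000L, burn_in = 500L), seed = 1)
  # prior_n_qtl = 1, M = 1 gives pi near 1; use M = 2 with a noise marker
  X2 <- cbind(x, noise = rbinom(50, 2, 0.5))
  est2 <- fit_bm(X2, y, bm_config(prior_n_qtl = 1L, prior_qtl_variance = 0.5,
                                  n_iter = 4000L, burn_in = 500L), seed = 1)
  ls_slope <- coef(lm(y ~ x))[2]
  expect_gt(est2$diagnostics$inclusion_prob[1], 0.9)
  expect_equal(unname(est2$effects[1]), unname(ls_slope), tolerance = 0.15)
  expect_equal(unname(est$effects[1]), unname(ls_slope), tolerance = 0.15)
})

test_that("BM inclusion probability calibrates to the prior under the null", {
  pi0 <- 0.1
  incl <- vapply(1:8, function(s) {
    set.seed(s)
    X <- matrix(rbinom(80 * 40, 2, 0.4), 80, 40)
    y <- rnorm(80)
    est <- fit_bm(X, y, bm_config(prior_n_qtl = 4L,   # pi = 4/40 = 0.1
                                  n_iter = 1500L, burn_in = 300L),
                  seed = s + 100)
    mean(est$diagnostics$inclusion_prob)
  }, numeric(1))
  expect_lt(abs(mean(incl) - pi0), 0.05)
})

test_that("BM shrinks effects relative to simple regression slopes", {
  # orthogonal predictors so the per-marker full conditional sees exactly
  # the simple-regression signal; the mixture prior can only shrink it
  set.seed(3)
  X <- qr.Q(qr(scale(matrix(rnorm(120 * 5), 120, 5), scale = FALSE))) * 5
  y <- drop(X %*% c(2, -1, 0.5, 0, 0)) + rnorm(120)
  est <- fit_bm(X, y, bm_config(prior_n_qtl = 2L,
                                n_iter = 3000L, burn_in = 500L),
                seed = 2)
  simple <- vapply(1:5, function(j) coef(lm(y ~ X[, j]))[2], numeric(1))
  expect_true(all(abs(est$effects) <= abs(simple) + 0.02))
})

test_that("BM is invariant to phenotype scale and deterministic in the seed", {
  toy <- make_regression_toy(60, 8, c(1.5, rep(0, 7)), seed = 4)
  cfgb <- bm_config(prior_n_qtl = 2L, n_iter = 1000L, burn_in = 200L)
  e1 <- fit_bm(toy$X, toy$y, cfgb, seed = 7)
  e2 <- fit_bm(toy$X, toy$y * 1000, cfgb, seed = 7)
  expect_equal(e2$effects, e1$effects * 1000, tolerance = 1e-10)
  e3 <- fit_bm(toy$X, toy$y, cfgb, seed = 7)
  expect_identical(e1$effects, e3$effects)
  # zero-variance columns are retained with zero effect
  Xz <- cbind(toy$X, const = 1)
  ez <- fit_bm(Xz, toy$y, cfgb, seed = 7)
  expect_equal(unname(ez$effects[9]), 0)
})

test_that("the per-marker-variance BM variant recovers strong signals too", {
  set.seed(25)
  x <- rbinom(60, 2, 0.5)
  X <- cbind(x, noise = rbinom(60, 2, 0.5))
  y <- 1.5 * x + rnorm(60, 0, 0.5)
  est <- fit_bm(X, y, bm_config(prior_n_qtl = 1L, n_iter = 2000L,
                                burn_in = 400L, variance_model = "marker"),
                seed = 5)
  expect_gt(est$diagnostics$inclusion_prob[1], 0.8)
  expect_equal(unname(est$effects[1]), unname(coef(lm(y ~ x))[2]),
               tolerance = 0.2)
})

## ---------------------------------------------------------------- LARS --

test_that("LARS on an orthonormal design soft-thresholds least squares", {
  set.seed(31)
  n <- 20; M <- 5
  Z <- scale(matrix(rnorm(n * M), n, M), scale = FALSE)
  X <- qr.Q(qr(Z))                      # orthonormal, zero-mean columns
  y <- rnorm(n)
  path <- lars_path(X, y, normalize = FALSE)
  cvec <- drop(crossprod(X, y - mean(y)))
  thresh <- c(sort(abs(cvec), decreasing = TRUE)[-1], 0)
  for (k in seq_len(M)) {
    ord <- order(abs(cvec), decreasing = TRUE)[seq_len(k)]
    oracle <- numeric(M)
    oracle[ord] <- sign(cvec[ord]) * (abs(cvec[ord]) - thresh[k])
    expect_equal(path$beta[k + 1L, ], oracle, tolerance = 1e-8)
  }
})

test_that("LARS path starts at zero, reduces RSS, and ends at least squares", {
  toy <- make_regression_toy(30, 5, c(1, -2, 0, 0.5, 0), seed = 5)
  path <- lars_path(toy$X, toy$y)
  expect_equal(path$beta[1L, ], rep(0, 5))
  Xc <- scale(toy$X, scale = FALSE)
  rss <- apply(path$beta, 1L, function(b)
    sum((toy$y - mean(toy$y) - Xc %*% b)^2))
  expect_true(all(diff(rss) <= 1e-8))
  ols <- coef(lm(toy$y ~ toy$X))[-1]
  expect_equal(unname(path$beta[nrow(path$beta), ]), unname(ols),
               tolerance = 1e-8)
})

test_that("LARS skips exactly collinear entrants", {
  # the duplicate of the strongest predictor ties at the top of the path,
  # is offered as the second entrant, and must be skipped
  set.seed(6)
  x1 <- rnorm(40); x3 <- rnorm(40)
  y <- 3 * x1 + 0.5 * x3 + rnorm(40)
  X <- cbind(x1, dup = x1, x3)
  expect_warning(path <- lars_path(X, y), "collinear")
  expect_equal(path$n_steps, 2L)
  expect_setequal(path$active, c(1L, 3L))
  expect_equal(path$beta[nrow(path$beta), 2L], 0)
  # a pure-duplicate design with n > M still ends at the least-squares
  # fit of the independent columns, duplicate untouched
  toy <- make_regression_toy(40, 3, c(1, 0.5, -1), seed = 6)
  X2 <- cbind(toy$X, dup = toy$X[, 1])
  p2 <- lars_path(X2, toy$y)
  ols <- coef(lm(toy$y ~ toy$X))[-1]
  expect_equal(unname(p2$beta[nrow(p2$beta), 1:3] +
                        c(p2$beta[nrow(p2$beta), 4], 0, 0)),
               unname(ols), tolerance = 1e-6)
})

test_that("cross-validated LARS selects a step and is deterministic", {
  toy <- make_regression_toy(60, 20, c(3, -3, 2, rep(0, 17)), seed = 7)
  e1 <- fit_lars(toy$X, toy$y, seed = 11)
  e2 <- fit_lars(toy$X, toy$y, seed = 11)
  expect_identical(e1$effects, e2$effects)
  expect_gte(e1$diagnostics$step, 1L)
  expect_length(e1$diagnostics$cv_error, min(59, 20) + 1L)
  # the three true predictors dominate the selected model
  big <- order(abs(e1$effects), decreasing = TRUE)[1:3]
  expect_setequal(big, 1:3)
  # scale equivariance
  e3 <- fit_lars(toy$X, toy$y * 1000, seed = 11)
  expect_equal(e3$effects, e1$effects * 1000, tolerance = 1e-8)
})

## ---------------------------------------------------------------- PLSR --

test_that("PLS1 with one component equals simple regression on one marker", {
  set.seed(41)
  x <- rbinom(80, 2, 0.5)
  y <- 2 * x + rnorm(80)
  fit <- pls1_fit(cbind(x), y, 1L)
  expect_equal(unname(pls1_coefficients(fit, 1L)),
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
})

test_that("PLS1 scores are orthogonal and the full fit reaches least squares", {
  set.seed(42)
  X <- matrix(rnorm(100 * 50), 100, 50)
  y <- rnorm(100)
  fit <- pls1_fit(X, y, 30L)
  G <- crossprod(fit$scores)
  off <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                       diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(off), 1e-8)
  # least-squares limit on a full-rank instance with M < n
  toy <- make_regression_toy(25, 10, rnorm(10), seed = 8)
  f2 <- pls1_fit(toy$X, toy$y, 10L)
  expect_equal(unname(pls1_coefficients(f2, 10L)),
               unname(coef(lm(toy$y ~ toy$X))[-1]), tolerance = 1e-6)
})

test_that("PLSR block search escalates the ceiling when needed", {
  set.seed(43)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- drop(X %*% rnorm(30))            # noiseless: many components help
  est <- fit_plsr(X, y, block = 2L, cv_folds = 5L, seed = 9)
  expect_gt(est$diagnostics$ceiling, 2L)
  expect_gte(est$diagnostics$ncomp, 2L)
  # deterministic and scale-equivariant
  e1 <- fit_plsr(X, y, seed = 10)
  e2 <- fit_plsr(X, y, seed = 10)
  expect_identical(e1$effects, e2$effects)
  e3 <- fit_plsr(X, y * 1000, seed = 10)
  expect_equal(e3$effects, e1$effects * 1000, tolerance = 1e-8)
})

## ------------------------------------------------------- predict_mebv --

test_that("MEBV are centered genotype deviations times effects", {
  est <- mebvsim:::new_effect_estimate("LARS", 2, center = 1, intercept = 5)
  expect_equal(predict_mebv(cbind(c(0, 1, 2)), est), c(-2, 0, 2))
  expect_equal(predict_mebv(cbind(c(0, 1, 2)), est, include_intercept = TRUE),
               c(3, 5, 7))
  est0 <- mebvsim:::new_effect_estimate("PLSR", rep(0, 3), rep(1, 3), 0)
  expect_equal(predict_mebv(matrix(2, 4, 3), est0), rep(0, 4))
  expect_error(predict_mebv(matrix(0, 2, 2), est), "column count")
  # full least-squares step reproduces centered fitted values
  toy <- make_regression_toy(30, 5, c(1, 2, -1, 0, 3), seed = 12)
  path <- lars_path(toy$X, toy$y)
  est_ls <- mebvsim:::new_effect_estimate(
    "LARS", path$beta[nrow(path$beta), ], colMeans(toy$X), mean(toy$y))
  fitted_centered <- fitted(lm(toy$y ~ toy$X)) - mean(toy$y)
  expect_equal(predict_mebv(toy$X, est_ls), unname(fitted_centered),
               tolerance = 1e-8)
})

test_that("the three methods agree on an idealized architecture", {
  # 20 strong independent markers, h2 = 0.5, n = 400 + 400
  set.seed(44)
  p <- runif(20, 0.3, 0.7)
  X <- hw_genotypes(800, p)
  a <- rnorm(20, 0, 1)
  tbv <- drop(X %*% a)
  y <- tbv + rnorm(800, 0, sd(tbv))
  tr <- 1:400; ev <- 401:800
  accs <- c(
    BM = accuracy(predict_mebv(X[ev, ], fit_bm(
      X[tr, ], y[tr], bm_config(prior_n_qtl = 10L, n_iter = 1500L,
                                burn_in = 300L), seed = 1)), tbv[ev]),
    LARS = accuracy(predict_mebv(X[ev, ], fit_lars(
      X[tr, ], y[tr], seed = 2)), tbv[ev]),
    PLSR = accuracy(predict_mebv(X[ev, ], fit_plsr(
      X[tr, ], y[tr], seed = 3)), tbv[ev]))
  expect_lt(max(accs) - min(accs), 0.05)
  expect_true(all(accs > 0.8))
})
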