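test_that("kernels have their defining values, limits and PSD Gram matrices", {
  x <- c(1, -2, 0.5)
  xp <- c(0, 1, 2)
  m52 <- kernel_spec("matern52", sigma2 = 1.7, lengthscale = 0.8,
                     noise_variance = 0.05)
  se <- kernel_spec("squared_exponential", sigma2 = 2.1, lengthscale = 1.2,
                    noise_variance = 0.05)
  lin <- kernel_spec("linear", sigma2 = 0.6, noise_variance = 0.05)

  expect_equal(kernel_eval(m52, x, x), 1.7, tolerance = 1e-12)
  expect_equal(kernel_eval(se, x, x), 2.1, tolerance = 1e-12)
  expect_lt(kernel_eval(se, x, x + 1e4), 1e-12)        # r -> Inf decays to 0
  expect_equal(kernel_eval(lin, 3 * x, 3 * xp), 9 * kernel_eval(lin, x, xp),
               tolerance = 1e-12)                      # k(cx, cx') = c^2 k
  expect_error(kernel_eval(m52, x, c(1, 2)), "dimension")

  # direct Matern-5/2 formula at one pair
  r <- sqrt(sum((x - xp)^2))
  a <- sqrt(5) * r / 0.8
  expect_equal(kernel_eval(m52, x, xp), 1.7 * (1 + a + a^2 / 3) * exp(-a),
               tolerance = 1e-12)

  P <- matrix(rnorm(15), 5, 3)
  for (spec in list(m52, se, lin)) {
    ev <- eigen(kernel_matrix(spec, P), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
  }
})

test_that("the log marginal likelihood matches a dense-algebra reimplementation", {
  set.seed(21)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- rnorm(20)
  for (kind in c("matern52", "squared_exponential", "linear")) {
    spec <- kernel_spec(kind, sigma2 = 1.3, lengthscale = 0.9,
                        noise_variance = 0.2)
    K <- kernel_matrix(spec, X) + diag(0.2, 20)
    oracle <- -0.5 * drop(t(y) %*% solve(K, y)) -
      0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
      10 * log(2 * pi)
    expect_equal(gp_log_marginal_likelihood(X, y, spec), oracle,
                 tolerance = 1e-8)
  }
})

test_that("linear-kernel GP equals closed-form Bayesian linear regression", {
  set.seed(33)
  n <- 50; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  w <- rnorm(d)
  y <- drop(X %*% w) + rnorm(n, sd = 0.3)
  y <- (y - mean(y)) / sd(y)
  sigma2 <- 0.8; noise <- 0.15
  spec <- kernel_spec("linear", sigma2 = sigma2, noise_variance = noise)
  fit <- gp_fit(X, y, kind = "linear", optimize = FALSE, init = spec)
  Xs <- matrix(rnorm(10 * d), 10, d)
  pr <- gp_predict(fit, Xs)

  # independent oracle: weight-space normal equations,
  # posterior mean = Xs (X'X + (noise/sigma2) I)^{-1} X' y
  A <- crossprod(X) + diag(noise / sigma2, d)
  w_post <- solve(A, crossprod(X, y))
  expect_equal(pr$mean, drop(Xs %*% w_post), tolerance = 1e-6)
  # predictive variance = noise + noise * xs' A^{-1} xs
  v_oracle <- noise + noise * rowSums(Xs * t(solve(A, t(Xs))))
  expect_equal(pr$variance, v_oracle, tolerance = 1e-6)
})

test_that("MAP optimization never degrades the objective and survives duplicates", {
  set.seed(44)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- sin(X[, 1]) + rnorm(40, sd = 0.2)
  y <- (y - mean(y)) / sd(y)
  for (kind in c("matern52", "squared_exponential", "linear")) {
    fit <- gp_fit(X, y, kind = kind, seed = 1)
    expect_gte(fit$objective_final, fit$objective_initial)
  }
  # duplicate inputs with conflicting labels: noise term regularizes
  Xd <- rbind(X[1:10, ], X[1:10, ])
  yd <- c(y[1:10], -y[1:10])
  expect_s3_class(gp_fit(Xd, yd, kind = "matern52", seed = 1), "gp_fit")
})

test_that("GP posterior interpolates at low noise and reverts to the prior far away", {
  set.seed(55)
  X <- matrix(seq(-2, 2, length.out = 25), ncol = 1)
  y <- sin(2 * X[, 1])
  spec <- kernel_spec("matern52", sigma2 = 1, lengthscale = 1,
                      noise_variance = 0.01)
  fit <- gp_fit(X, y, kind = "matern52", optimize = FALSE, init = spec)
  pr_tr <- gp_predict(fit, X)
  expect_lt(mean(abs(pr_tr$mean - y)), 0.1)    # near-interpolation at the floor

  pr_far <- gp_predict(fit, matrix(1e3, 1, 1))
  expect_equal(pr_far$variance, 1 + 0.01, tolerance = 1e-6)   # sigma2 + noise
  expect_equal(pr_far$mean, 0, tolerance = 1e-6)

  # linear kernel: prior variance grows with the input norm
  lfit <- gp_fit(X, y, kind = "linear", optimize = FALSE,
                 init = kernel_spec("linear", sigma2 = 1, noise_variance = 0.1))
  v <- gp_predict(lfit, matrix(c(10, 100, 1000), 3, 1))$variance
  expect_true(all(diff(v) > 0))
})

test_that("MAP noise variance is recoverable from SE-kernel draws", {
  # lighter companion to the full recovery study: 5 seeds, n = 120
  ratios <- sapply(1:5, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(120 * 2), 120, 2)
    spec <- kernel_spec("squared_exponential", sigma2 = 1, lengthscale = 1.5,
                        noise_variance = 0.1)
    y <- gp_prior_sample(X, spec, seed = s)$y
    y <- y / sd(y)
    fit <- gp_fit(X, y, kind = "squared_exponential", seed = s, n_restarts = 2)
    fit$spec$noise_variance / 0.1
  })
  expect_lt(median(ratios), 3)
  expect_gt(median(ratios), 1 / 3)
})

test_that("kNN prediction follows the neighbour-mean contract with tie rule", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  y <- c(1, 3, 5, 100)
  pr_all <- knn_fit_predict(X, y, matrix(c(0.4, 5), ncol = 1), k = 4)
  expect_equal(pr_all$mean, rep(mean(y), 2))          # k = n: global mean

  pr1 <- knn_fit_predict(X, y, matrix(1.1, 1, 1), k = 1)
  expect_equal(pr1$mean, 3)                           # nearest neighbour
  expect_equal(pr1$variance, 1e-12)                   # floored variance

  # equidistant neighbours: lowest training index wins
  Xt <- matrix(c(-1, 1), ncol = 1)
  pr_tie <- knn_fit_predict(Xt, c(7, 9), matrix(0, 1, 1), k = 1)
  expect_equal(pr_tie$mean, 7)
  expect_error(knn_fit_predict(X, y, X, k = 5), "k must")
})

test_that("RF variance is the across-tree second moment minus squared mean", {
  m <- fitscape:::ensemble_moments(rbind(c(0, 2), c(1, 1)))
  expect_equal(m$mean, c(1, 1))
  expect_equal(m$variance, c(1, 0))   # (0 + 4)/2 - 1 = 1; degenerate -> 0

  set.seed(66)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- X[, 1] + rnorm(60, sd = 0.1)
  p1 <- rf_fit_predict(X, y, X[1:5, ], n_estimators = 50, seed = 9)
  p2 <- rf_fit_predict(X, y, X[1:5, ], n_estimators = 50, seed = 9)
  expect_identical(p1$mean, p2$mean)                  # seeded determinism
  expect_true(all(p1$variance >= 0))

  # constant labels: every tree agrees, variance collapses to the floor
  pc <- rf_fit_predict(X, rep(2, 60), X[1:3, ], n_estimators = 20, seed = 1)
  expect_equal(pc$mean, rep(2, 3), tolerance = 1e-12)
  expect_equal(pc$variance, rep(1e-12, 3))
})

test_that("hyperparameter search is exhaustive within budget and in range", {
  set.seed(77)
  X <- matrix(rnorm(45), ncol = 1)
  y <- drop(X) + rnorm(45, sd = 0.2)
  k_max <- floor(0.95 * 45 / 3)   # 14 < budget 75 -> exhaustive
  k <- tune_knn(X, y, seed = 1)
  expect_true(k >= 1 && k <= k_max)
  # brute-force the same internal-CV objective over the full range
  cv_seed <- fitscape:::derive_seed(1, 11)
  maes <- sapply(seq_len(k_max), function(kk) {
    fitscape:::internal_cv_mae(X, y, function(Xtr, ytr, Xte) {
      knn_fit_predict(Xtr, ytr, Xte, k = min(kk, length(ytr)))
    }, seed = cv_seed)
  })
  expect_equal(k, which.min(maes))

  m <- tune_rf(X, y, seed = 2)
  expect_true(m >= 2 && m <= 45)
  expect_warning(tune_knn(X[1:4, , drop = FALSE], y[1:4], seed = 1), "default")
})

test_that("tuned k beats the one-third-of-N default on locally structured data", {
  res <- sapply(1:10, function(s) {
    set.seed(2000 + s)
    n <- 60
    X <- matrix(runif(n, 0, 10), ncol = 1)
    y <- floor(X[, 1]) + rnorm(n, sd = 0.05)   # piecewise-constant landscape
    Xte <- matrix(runif(40, 0, 10), ncol = 1)
    yte <- floor(Xte[, 1])
    k_tuned <- tune_knn(X, y, seed = s)
    k_default <- ceiling(n / 3)
    mae <- function(k) mean(abs(yte - knn_fit_predict(X, y, Xte, k)$mean))
    mae(k_default) - mae(k_tuned)
  })
  expect_gt(median(res), 0)
})

test_that("surrogate-assisted search respects the budget on large ranges", {
  calls <- 0L
  noisy_obj <- function(k) {
    calls <<- calls + 1L
    (k - 137)^2 / 1e4 + sin(k / 7) * 0.05
  }
  best <- fitscape:::surrogate_search(1:500, budget = 30, noisy_obj, seed = 3)
  expect_lte(calls, 30)
  expect_true(best %in% 1:500)
  # the surrogate should get reasonably close to the true minimum basin
  expect_lt(abs(best - 137), 150)
})

test_that("all regressors honor the predictive-distribution contract", {
  set.seed(88)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(40, sd = 0.3) + 5
  Xs <- matrix(rnorm(12 * 4), 12, 4)
  for (kind in c("mean", "knn", "rf", "gp-lin", "gp-se", "gp-m52")) {
    fp <- fit_predict_regressor(kind, X, y, Xs, seed = 1,
                                optimize_hparams = FALSE)
    expect_true(all(is.finite(fp$pred$mean)), info = kind)
    expect_true(all(fp$pred$variance >= 0), info = kind)
    expect_length(fp$pred$mean, 12)
    # de-standardization round-trip: predictions on the original label scale
    expect_lt(abs(mean(fp$pred$mean) - 5), 4, label = kind)
  }
})
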