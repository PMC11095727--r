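#' k-nearest-neighbour regression with neighbour-label variance
#'
#' A non-parametric, deterministic baseline regressor. The prediction at a
#' query is the mean of its k nearest training labels (Euclidean distance in
#' representation space); its predictive variance is the empirical variance of
#' those k labels, floored at 1e-12. Distance ties are broken by the lowest
#' training index. kNN is characteristically under-dispersed: its variance
#' reflects only local label spread, not distance from the data, and no
#' inflation is applied.
#'
#' @param X n x d training inputs.
#' @param y training labels.
#' @param Xstar m x d query inputs.
#' @param k number of neighbours, 1 <= k <= n.
#' @return a predictive distribution (list with `mean`, `variance`).
#' @export
knn_fit_predict <- function(X, y, Xstar, k) {
  X <- as.matrix(X); Xstar <- as.matrix(Xstar)
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  D <- sq_dist(Xstar, X)
  mu <- numeric(nrow(Xstar))
  v <- numeric(nrow(Xstar))
  for (i in seq_len(nrow(Xstar))) {
    nb <- order(D[i, ], seq_len(n))[seq_len(k)]   # ties -> lowest index
    lab <- y[nb]
    mu[i] <- mean(lab)
    v[i] <- if (k > 1L) stats::var(lab) * (k - 1) / k else 0
  }
  new_predictive(mu, v)
}

# Across-tree ensemble moments: mean and (population) variance of per-tree
# predictions, the predictive uncertainty extension of the random forest.
ensemble_moments <- function(pred_matrix) {
  mu <- rowMeans(pred_matrix)
  v <- rowMeans(pred_matrix^2) - mu^2
  list(mean = mu, variance = pmax(v, 0))
}

#' Random-forest regression with across-tree predictive variance
#'
#' Fits a random forest (via \pkg{ranger}) and augments the usual across-tree
#' mean with a predictive variance: the across-tree second moment minus the
#' squared across-tree mean of the per-tree predictions.
#'
#' @param X n x d training inputs.
#' @param y training labels.
#' @param Xstar m x d query inputs.
#' @param n_estimators number of trees (>= 2).
#' @param seed integer seed (forest growth is deterministic given it).
#' @return a predictive distribution.
#' @export
rf_fit_predict <- function(X, y, Xstar, n_estimators = 100L, seed = 1L) {
  if (n_estimators < 2L) stop("n_estimators must be >= 2")
  X <- as.matrix(X); Xstar <- as.matrix(Xstar)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(Xstar) <- colnames(X)
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_estimators, seed = as.integer(seed),
                        num.threads = 1L)
  pr <- stats::predict(fit, data.frame(Xstar, check.names = FALSE),
                       predict.all = TRUE, num.threads = 1L)
  m <- ensemble_moments(pr$predictions)
  new_predictive(m$mean, m$variance)
}

# Internal 3-fold CV mean absolute error of a candidate hyperparameter.
internal_cv_mae <- function(X, y, fit_fun, seed) {
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(1:3, n)))
  errs <- vapply(1:3, function(f) {
    te <- which(folds == f); tr <- which(folds != f)
    p <- fit_fun(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
    mean(abs(y[te] - p$mean))
  }, 0)
  mean(errs)
}

# Budget-limited search over an integer grid, minimizing internal-CV MAE.
# Exhaustive when the grid fits in the budget; otherwise surrogate-assisted
# (Matern-5/2 GP over the log-scaled grid, expected-improvement acquisition).
surrogate_search <- function(grid, budget, eval_fun, seed) {
  grid <- sort(unique(grid))
  if (length(grid) <= budget) {
    vals <- vapply(grid, eval_fun, 0)
    return(grid[which.min(vals)])
  }
  z <- matrix(log(grid), ncol = 1L)
  z <- (z - min(z)) / (max(z) - min(z))
  n_init <- min(max(5L, budget %/% 5L), budget)
  evaluated <- with_seed(seed, {
    idx <- unique(round(seq(1L, length(grid), length.out = n_init)))
    idx
  })
  vals <- vapply(evaluated, function(i) eval_fun(grid[i]), 0)
  while (length(evaluated) < budget) {
    spec <- kernel_spec("matern52", sigma2 = max(stats::var(vals), 1e-6),
                        lengthscale = 0.2, noise_variance = 0.01)
    std <- tryCatch(fit_standardizer(vals), error = function(e) NULL)
    if (is.null(std)) break   # all evaluations identical; nothing to learn
    fit <- gp_fit(z[evaluated, , drop = FALSE], apply_standardizer(std, vals),
                  kind = "matern52", optimize = FALSE, init = spec)
    cand <- setdiff(seq_along(grid), evaluated)
    pr <- gp_predict(fit, z[cand, , drop = FALSE])
    # minimize MAE == maximize improvement over -best on negated values
    ei <- expected_improvement(-pr$mean, sqrt(pr$variance),
                               best = max(-apply_standardizer(std, vals)))
    pick <- cand[which.max(ei)]
    evaluated <- c(evaluated, pick)
    vals <- c(vals, eval_fun(grid[pick]))
  }
  grid[evaluated[which.min(vals)]]
}

#' Tune the kNN neighbour count
#'
#' Minimizes the internal three-fold cross-validated mean absolute error over
#' k in [1, floor(0.95 N / 3)] with an evaluation budget of 75 (exhaustive
#' when the range is within budget, surrogate-assisted otherwise). With fewer
#' than 6 training points the default k = ceiling(N / 3) is returned with a
#' warning.
#'
#' @param X training inputs.
#' @param y training labels.
#' @param seed integer seed.
#' @param budget evaluation budget (default 75).
#' @return the selected integer k.
#' @export
tune_knn <- function(X, y, seed = 1L, budget = 75L) {
  n <- length(y)
  k_default <- max(1L, min(n, ceiling(n / 3)))
  if (n < 6L) {
    warning("too few points for internal 3-fold CV; using default k = ", k_default)
    return(k_default)
  }
  k_max <- max(1L, floor(0.95 * n / 3))
  cv_seed <- derive_seed(seed, 11L)
  eval_fun <- function(k) {
    internal_cv_mae(X, y, function(Xtr, ytr, Xte) {
      knn_fit_predict(Xtr, ytr, Xte, k = min(k, length(ytr)))
    }, seed = cv_seed)
  }
  surrogate_search(seq_len(k_max), budget, eval_fun, seed = derive_seed(seed, 13L))
}

#' Tune the random-forest tree count
#'
#' Minimizes internal three-fold cross-validated MAE over n_estimators in
#' [2, N] with an evaluation budget of 15.
#'
#' @inheritParams tune_knn
#' @param budget evaluation budget (default 15).
#' @return the selected number of trees.
#' @export
tune_rf <- function(X, y, seed = 1L, budget = 15L) {
  n <- length(y)
  if (n < 6L) {
    warning("too few points for internal 3-fold CV; using default n_estimators = 100")
    return(100L)
  }
  cv_seed <- derive_seed(seed, 17L)
  eval_fun <- function(m) {
    internal_cv_mae(X, y, function(Xtr, ytr, Xte) {
      rf_fit_predict(Xtr, ytr, Xte, n_estimators = m, seed = derive_seed(seed, m))
    }, seed = cv_seed)
  }
  surrogate_search(2:n, budget, eval_fun, seed = derive_seed(seed, 19L))
}
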