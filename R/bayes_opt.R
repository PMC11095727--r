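#' Expected improvement acquisition value
#'
#' Maximization convention: EI = (mu - best) * Phi(z) + sigma * phi(z) with
#' z = (mu - best) / sigma for sigma > 0, and EI = max(mu - best, 0) at
#' sigma = 0. No exploration jitter (xi = 0). Vectorized over candidates.
#'
#' @param mu predicted means.
#' @param sigma predictive standard deviations (>= 0).
#' @param best incumbent (best observed) value.
#' @return non-negative EI values.
#' @export
expected_improvement <- function(mu, sigma, best) {
  stopifnot(all(sigma >= 0))
  d <- mu - best
  out <- pmax(d, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- d[pos] / sigma[pos]
    out[pos] <- d[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

new_bo_trace <- function(seed, init_indices, selected, best_so_far, found_at,
                         method) {
  stopifnot(all(diff(best_so_far) >= -1e-12), !anyDuplicated(selected))
  structure(list(seed = seed, init_indices = init_indices, selected = selected,
                 best_so_far = best_so_far, found_at = found_at,
                 method = method),
            class = "bo_trace")
}

#' @export
print.bo_trace <- function(x, ...) {
  cat("BO trace [", x$method, "] seed ", x$seed, ": ", length(x$selected),
      " iterations, best = ", signif(max(x$best_so_far), 4),
      ", optimum found at ",
      if (is.na(x$found_at)) "never" else x$found_at, "\n", sep = "")
  invisible(x)
}

#' Bayesian-optimization assessment loop over a labelled candidate pool
#'
#' Optimization-as-assessment: all pool labels are known, and the task is to
#' find the pool optimum in as few acquisitions as possible. Starting from
#' `n_init` uniformly random pool points, each iteration refits the surrogate
#' regressor (including its hyperparameter protocol) on the observed points,
#' scores every unobserved candidate by expected improvement, selects the
#' argmax (ties broken by lowest index), and reveals its label.
#'
#' @param X pool representation matrix (one row per candidate).
#' @param y pool labels (revealed on selection).
#' @param regressor surrogate kind: `"knn"`, `"rf"`, `"gp-lin"`, `"gp-se"`,
#'   or `"gp-m52"`.
#' @param budget maximum number of acquisitions after initialization
#'   (default 500).
#' @param n_init initial random observations (default 5).
#' @param seed integer seed (controls the initial ordering).
#' @param optimize_hparams run the per-iteration hyperparameter protocol
#'   (default `TRUE`).
#' @param refit_every refit the surrogate every this many iterations
#'   (default 1, i.e. every iteration; larger values are a desk-scale
#'   throttle).
#' @param n_restarts restarts for GP hyperparameter optimization.
#' @return a `bo_trace`.
#' @export
bo_loop <- function(X, y, regressor = "gp-m52", budget = 500L, n_init = 5L,
                    seed = 1L, optimize_hparams = TRUE, refit_every = 1L,
                    n_restarts = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (budget < 1L) stop("budget must be >= 1")
  if (n_init < 1L || n_init > n) stop("pool smaller than n_init")
  opt_idx <- which.max(y)

  observed <- with_seed(seed, sample.int(n, n_init))
  selected <- integer(0)
  best <- max(y[observed])
  best_so_far <- numeric(0)
  found_at <- if (opt_idx %in% observed) 0L else NA_integer_
  model <- NULL
  it <- 0L
  while (it < budget && length(observed) + length(selected) < n) {
    it <- it + 1L
    seen <- c(observed, selected)
    cand <- setdiff(seq_len(n), seen)
    if (is.null(model) || (it - 1L) %% refit_every == 0L) {
      model <- tryCatch(
        fit_regressor(regressor, X[seen, , drop = FALSE], y[seen],
                      seed = derive_seed(seed, it),
                      optimize_hparams = optimize_hparams,
                      n_restarts = n_restarts),
        error = function(e) {
          # too few / constant observations: fall back to an uninformative
          # surrogate (constant mean, unit variance), for which EI ties and
          # the lowest-index candidate is taken
          mu <- mean(y[seen])
          list(predict = function(Xstar) {
            m <- nrow(as.matrix(Xstar))
            new_predictive(rep.int(mu, m), rep.int(1, m))
          })
        })
    }
    pred <- model$predict(X[cand, , drop = FALSE])
    ei <- expected_improvement(pred$mean, sqrt(pred$variance), best)
    pick <- cand[order(-ei, cand)[1L]]   # ties -> lowest index
    selected <- c(selected, pick)
    best <- max(best, y[pick])
    best_so_far <- c(best_so_far, best)
    if (is.na(found_at) && pick == opt_idx) found_at <- it
  }
  new_bo_trace(seed, observed, selected, best_so_far, found_at,
               method = regressor)
}

#' Random-selection baseline trace
#'
#' Selects a uniformly random unobserved candidate at each iteration; the
#' reference against which surrogate-guided acquisition is judged.
#'
#' @inheritParams bo_loop
#' @return a `bo_trace`.
#' @export
random_selection_trace <- function(X, y, budget = 500L, n_init = 5L,
                                   seed = 1L) {
  n <- length(y)
  if (budget < 1L) stop("budget must be >= 1")
  if (n_init < 1L || n_init > n) stop("pool smaller than n_init")
  opt_idx <- which.max(y)
  with_seed(seed, {
    perm <- sample.int(n)
    observed <- perm[seq_len(n_init)]
    picks <- perm[(n_init + 1L):min(n, n_init + budget)]
    best <- max(y[observed])
    best_so_far <- cummax(c(best, y[picks]))[-1L]
    found_at <- if (opt_idx %in% observed) 0L
                else match(opt_idx, picks)
    new_bo_trace(seed, observed, picks, best_so_far,
                 if (is.na(found_at)) NA_integer_ else as.integer(found_at),
                 method = "random")
  })
}

#' Summarize BO traces over quarters of the iteration axis
#'
#' Reports, at each partition boundary ceiling(budget * j / n_partitions),
#' the mean and standard error across traces of the best-so-far value, plus
#' the median iteration at which the pool optimum was found.
#'
#' @param traces list of `bo_trace` objects.
#' @param n_partitions number of partitions (default 4).
#' @return list with a `quarters` data.frame (`iteration`, `mean_best`,
#'   `se_best`) and `median_iterations_to_optimum`.
#' @export
summarize_traces <- function(traces, n_partitions = 4L) {
  stopifnot(length(traces) >= 1L)
  budget <- max(vapply(traces, function(t) length(t$best_so_far), 0L))
  bounds <- unique(pmax(1L, ceiling(budget * seq_len(n_partitions) / n_partitions)))
  at <- function(t, i) {
    b <- t$best_so_far
    b[min(i, length(b))]
  }
  rows <- lapply(bounds, function(i) {
    v <- vapply(traces, at, 0, i = i)
    data.frame(iteration = as.integer(i), mean_best = mean(v),
               se_best = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0)
  })
  iters <- vapply(traces, function(t) as.numeric(t$found_at), 0)
  list(quarters = do.call(rbind, rows),
       median_iterations_to_optimum = stats::median(iters, na.rm = FALSE))
}
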