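#' Kernel specifications for GP regression
#'
#' Three covariance functions:
#' \describe{
#'   \item{linear}{k(x, x') = sigma2 * <x, x'> (shared signal variance by
#'     default; per-dimension ARD variances optional). A GP with this kernel
#'     is Bayesian linear regression with prior weight variance sigma2.}
#'   \item{squared_exponential}{k(x, x') = sigma2 * exp(-r^2 / (2 l^2)),
#'     r = ||x - x'||.}
#'   \item{matern52}{k(x, x') = sigma2 * (1 + sqrt(5) r / l +
#'     5 r^2 / (3 l^2)) * exp(-sqrt(5) r / l).}
#' }
#'
#' @param kind one of `"linear"`, `"squared_exponential"`, `"matern52"`.
#' @param sigma2 signal variance (> 0); for the ARD linear kernel a vector of
#'   per-dimension variances.
#' @param lengthscale lengthscale l (> 0); ignored by the linear kernel.
#' @param noise_variance observation noise variance, constrained to
#'   [0.01, 1.0] (the support of its uniform prior on standardized labels).
#' @return object of class `"kernel_spec"`.
#' @export
kernel_spec <- function(kind = c("linear", "squared_exponential", "matern52"),
                        sigma2 = 1, lengthscale = 1, noise_variance = 0.1) {
  kind <- match.arg(kind)
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  if (kind != "linear" && lengthscale <= 0) stop("lengthscale must be > 0")
  if (noise_variance < 0.01 || noise_variance > 1.0) {
    stop("noise_variance must lie in [0.01, 1.0]")
  }
  structure(list(kind = kind, sigma2 = sigma2,
                 lengthscale = if (kind == "linear") NULL else lengthscale,
                 noise_variance = noise_variance),
            class = "kernel_spec")
}

# Squared Euclidean cross-distances between rows of A and B.
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Evaluate a kernel between two single points
#'
#' @param spec a [kernel_spec()].
#' @param x,xp numeric vectors of equal dimension.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, xp) {
  if (length(x) != length(xp)) stop("dimension mismatch")
  kernel_matrix(spec, matrix(x, 1L), matrix(xp, 1L))[1L, 1L]
}

#' Kernel (Gram) matrix between row sets
#'
#' @param spec a [kernel_spec()].
#' @param A n x d matrix.
#' @param B m x d matrix (defaults to `A`, giving the n x n Gram matrix).
#' @return n x m kernel matrix.
#' @export
kernel_matrix <- function(spec, A, B = A) {
  if (ncol(A) != ncol(B)) stop("dimension mismatch")
  switch(spec$kind,
    linear = {
      if (length(spec$sigma2) == 1L) {
        spec$sigma2 * tcrossprod(A, B)
      } else {
        if (length(spec$sigma2) != ncol(A)) stop("ARD sigma2 length != d")
        tcrossprod(sweep(A, 2L, spec$sigma2, "*"), B)
      }
    },
    squared_exponential = {
      spec$sigma2 * exp(-sq_dist(A, B) / (2 * spec$lengthscale^2))
    },
    matern52 = {
      a <- sqrt(5) * sqrt(sq_dist(A, B)) / spec$lengthscale
      spec$sigma2 * (1 + a + a^2 / 3) * exp(-a)
    },
    stop("unknown kernel kind")
  )
}

# Cholesky with an escalating jitter ladder (relative to mean diagonal).
chol_jitter <- function(K, ladder = 10^seq(-8, -4)) {
  d <- mean(diag(K))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(ch)) return(list(L = ch, jitter = 0))
  for (j in ladder) {
    ch <- tryCatch(chol(K + diag(j * d, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) return(list(L = ch, jitter = j * d))
  }
  stop("Cholesky factorization failed after jitter escalation")
}
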