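#' One-hot encode variants of a wildtype sequence
#'
#' Each variant becomes a flattened binary vector of length `L * |alphabet|`
#' with exactly one indicator set per site (so every row sums to `L`). Two
#' variants differ in exactly two coordinates per site at which their residues
#' differ. Columns are ordered site-major in the frozen alphabet order of
#' [aa_alphabet()].
#'
#' @param variants character vector of mutation strings.
#' @param wildtype wildtype sequence.
#' @param alphabet ordered residue symbols; defaults to the 22-symbol extended
#'   alphabet (20 canonical + gap + unknown). Gap/unknown columns are
#'   constant-zero on clean substitution data but keep the layout compatible
#'   with gapped or partially characterized inputs.
#' @return numeric matrix, one row per variant, with attribute
#'   `source = "one_hot"`.
#' @export
one_hot_encode <- function(variants, wildtype, alphabet = aa_alphabet()) {
  wt <- strsplit(wildtype, "")[[1L]]
  L <- length(wt)
  d_aa <- length(alphabet)
  wt_idx <- match(wt, alphabet)
  if (anyNA(wt_idx)) stop("wildtype contains residues outside the alphabet")
  base_cols <- (seq_len(L) - 1L) * d_aa

  X <- matrix(0, nrow = length(variants), ncol = L * d_aa)
  wt_row <- numeric(L * d_aa)
  wt_row[base_cols + wt_idx] <- 1
  for (i in seq_along(variants)) {
    row <- wt_row
    subs <- parse_mutations(variants[i])
    if (nrow(subs)) {
      mut_idx <- match(subs$mut_aa, alphabet)
      if (anyNA(mut_idx)) {
        stop("variant '", variants[i], "': residue outside the alphabet")
      }
      row[base_cols[subs$pos] + wt_idx[subs$pos]] <- 0
      row[base_cols[subs$pos] + mut_idx] <- 1
    }
    X[i, ] <- row
  }
  colnames(X) <- paste0(rep(seq_len(L), each = d_aa), rep(alphabet, L))
  attr(X, "source") <- "one_hot"
  X
}

#' Mean-pool a per-position representation into one vector
#'
#' The standard aggregation for per-residue language-model states: the
#' coordinate-wise arithmetic mean over sequence positions.
#'
#' @param per_position an L x d numeric matrix (rows = positions).
#' @return numeric vector of length d.
#' @export
mean_pool <- function(per_position) {
  if (!is.matrix(per_position) || nrow(per_position) < 1L) {
    stop("per_position must be a matrix with at least one row")
  }
  colMeans(per_position)
}

#' Surrogate embeddings: a fixed random projection of the one-hot encoding
#'
#' Stands in for mean-pooled protein language-model embeddings: a
#' deterministic sequence-to-vector map of controllable dimension and
#' (non)linearity. The projection matrix is a fixed function of the seed, so
#' identical variants always get identical rows and the whole map is
#' reproducible.
#'
#' @param variants character vector of mutation strings.
#' @param wildtype wildtype sequence.
#' @param d embedding dimension (>= 1).
#' @param nonlinearity `"none"` (linear map; embeddings are additive in
#'   substitutions) or `"tanh"`.
#' @param seed integer seed fixing the projection.
#' @return n x d numeric matrix with attribute `source = "surrogate"`.
#' @export
surrogate_embedding <- function(variants, wildtype, d = 64L,
                                nonlinearity = c("none", "tanh"), seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(d >= 1L)
  X <- one_hot_encode(variants, wildtype)
  W <- with_seed(seed, {
    matrix(stats::rnorm(ncol(X) * d, sd = 1 / sqrt(ncol(X))), ncol(X), d)
  })
  E <- X %*% W
  if (nonlinearity == "tanh") E <- tanh(E)
  attr(E, "source") <- "surrogate"
  E
}

#' Read an external embedding matrix keyed to a variant table
#'
#' @param path delimited text file, one row per variant, numeric columns.
#' @param n_expected expected number of rows (e.g. rows of the variant CSV);
#'   validated if given.
#' @param sep field separator.
#' @return numeric matrix with attribute `source = "external"`.
#' @export
read_embedding <- function(path, n_expected = NULL, sep = ",") {
  M <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  storage.mode(M) <- "numeric"
  if (!all(is.finite(M))) stop("embedding contains non-finite entries")
  if (!is.null(n_expected) && nrow(M) != n_expected) {
    stop("embedding has ", nrow(M), " rows but ", n_expected, " were expected")
  }
  attr(M, "source") <- "external"
  M
}

#' Fit a training-fold label standardizer
#'
#' Labels are standardized on the training fold only (never on pooled data):
#' the transformed training labels have mean 0 and sd 1, matching the
#' zero-mean prior of the GP regressors and preventing test-set leakage.
#'
#' @param train_labels numeric vector, length >= 2, non-constant.
#' @return object of class `"label_standardizer"` with fields `mu`, `sd`.
#' @export
fit_standardizer <- function(train_labels) {
  if (length(train_labels) < 2L) stop("need at least 2 training labels")
  mu <- mean(train_labels)
  sd <- stats::sd(train_labels)
  if (!is.finite(sd) || sd <= 0) stop("training labels are constant; sd = 0")
  structure(list(mu = mu, sd = sd), class = "label_standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted standardizer.
#' @param y labels to transform / back-transform.
#' @export
apply_standardizer <- function(std, y) (y - std$mu) / std$sd

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(std, y) y * std$sd + std$mu
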