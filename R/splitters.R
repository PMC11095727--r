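#' Split plans
#'
#' A split plan is an ordered list of folds, each a disjoint pair of 1-based
#' train and test index vectors over the dataset rows, tagged with the
#' protocol that produced it.
#'
#' @param folds list of `list(train =, test =)` index pairs.
#' @param protocol protocol name.
#' @param params protocol parameters (list).
#' @param n number of dataset rows the indices refer to.
#' @return object of class `"split_plan"`.
#' @export
new_split_plan <- function(folds, protocol, params = list(), n = NULL) {
  for (f in folds) {
    if (length(intersect(f$train, f$test)) > 0L) {
      stop("train and test overlap within a fold")
    }
    if (!is.null(n) && length(c(f$train, f$test)) &&
        (max(c(f$train, f$test)) > n || min(c(f$train, f$test)) < 1L)) {
      stop("fold indices out of range")
    }
  }
  structure(list(folds = folds, protocol = protocol, params = params, n = n),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) {
    sprintf("%d/%d", length(f$train), length(f$test))
  }, "")
  cat("Split plan [", x$protocol, "]: ", length(x$folds),
      " folds (train/test sizes: ", paste(sizes, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Random k-fold cross-validation
#'
#' Shuffles the indices uniformly at random and partitions them into k folds
#' whose test sets are pairwise disjoint, cover every index, and differ in
#' size by at most one.
#'
#' @param n number of rows.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a `split_plan`.
#' @export
random_cv <- function(n, k = 10L, seed = 1L) {
  if (k < 2L || k > n) stop("k must lie in [2, n]")
  perm <- with_seed(seed, sample.int(n))
  assignment <- rep_len(seq_len(k), n)   # sizes differ by <= 1
  folds <- lapply(seq_len(k), function(f) {
    te <- sort(perm[assignment == f])
    list(train = setdiff(seq_len(n), te), test = te)
  })
  new_split_plan(folds, "random_cv", list(k = k, seed = seed), n = n)
}

#' Positional cross-validation over contiguous sequence blocks
#'
#' Partitions positions 1..L into contiguous blocks of size p (the final
#' block may be shorter), giving ceiling(L/p) folds. A variant belongs to
#' fold j's test set iff any of its mutated positions falls in block j, and
#' to the training set otherwise; the wildtype (degree 0) is always in train.
#' Training variants therefore never carry a mutation inside the held-out
#' block, probing generalization to unseen positions.
#'
#' @param variants character vector of mutation strings.
#' @param L sequence length.
#' @param p block size (default 15).
#' @return a `split_plan`.
#' @export
position_cv <- function(variants, L, p = 15L) {
  if (p < 1L || p > L) stop("p must lie in [1, L]")
  subs <- lapply(variants, parse_mutations)
  pos_list <- lapply(subs, `[[`, "pos")
  if (any(unlist(pos_list) > L | unlist(pos_list) < 1L)) {
    stop("variant position outside [1, L]")
  }
  n_folds <- ceiling(L / p)
  folds <- lapply(seq_len(n_folds), function(j) {
    lo <- (j - 1L) * p + 1L
    hi <- min(j * p, L)
    in_block <- vapply(pos_list, function(ps) any(ps >= lo & ps <= hi), TRUE)
    list(train = which(!in_block), test = which(in_block))
  })
  new_split_plan(folds, "position_cv", list(L = L, p = p),
                 n = length(variants))
}

#' Mutational (degree-extrapolation) cross-validation
#'
#' Tests generalization from lower to higher mutation degrees. With
#' `include_equal_degree = FALSE` there is a single fold: train on all
#' variants of degree < `test_degree`, test on all variants of exactly
#' `test_degree`. With `include_equal_degree = TRUE` (the in-domain diagonal),
#' the test-degree variants are partitioned into `n_folds_equal` folds; each
#' fold trains on all lower-degree variants plus the remaining ~80% of
#' test-degree variants and tests on the held-out ~20%, so every test-degree
#' variant is tested exactly once. Variants of higher degree never appear.
#'
#' @param variants character vector of mutation strings.
#' @param test_degree target degree (>= 1).
#' @param include_equal_degree see above.
#' @param n_folds_equal folds for the in-domain diagonal (default 5, i.e. 20%
#'   held out per fold).
#' @param seed integer seed.
#' @return a `split_plan`.
#' @export
mutational_cv <- function(variants, test_degree, include_equal_degree = FALSE,
                          n_folds_equal = 5L, seed = 1L) {
  deg <- variant_degree(variants)
  if (test_degree < 1L) stop("test_degree must be >= 1")
  te_all <- which(deg == test_degree)
  lower <- which(deg < test_degree & deg >= 1L)
  if (length(te_all) == 0L) stop("no variants of test_degree present")
  if (!include_equal_degree) {
    if (length(lower) == 0L) stop("empty training set: no lower-degree variants")
    plan <- list(list(train = lower, test = te_all))
  } else {
    perm <- with_seed(seed, sample(te_all))
    assignment <- rep_len(seq_len(n_folds_equal), length(perm))
    plan <- lapply(seq_len(n_folds_equal), function(f) {
      te <- sort(perm[assignment == f])
      list(train = sort(c(lower, setdiff(te_all, te))), test = te)
    })
  }
  new_split_plan(plan, "mutational_cv",
                 list(test_degree = test_degree,
                      include_equal_degree = include_equal_degree,
                      n_folds_equal = n_folds_equal, seed = seed),
                 n = length(variants))
}

#' Fractional cross-validation (learning-curve splits)
#'
#' For each repetition, holds out `ceiling(eval_frac * n)` indices uniformly
#' at random as a fixed test set, then for each fraction q trains on
#' `ceiling(q * n_remainder)` of the remaining indices. Keeping the test set
#' fixed across fractions within a repetition makes test difficulty constant
#' along the learning curve; `mode = "complement"` instead tests on the whole
#' non-training remainder.
#'
#' @param n number of rows.
#' @param fractions training fractions (default quartiles 0.25..1).
#' @param reps repetitions per fraction (default 5).
#' @param eval_frac held-out evaluation fraction (default 0.2).
#' @param mode `"fixed"` (fixed evaluation set) or `"complement"`.
#' @param seed integer seed.
#' @return a `split_plan` with `reps * length(fractions)` folds, ordered by
#'   repetition then fraction; each fold's params are recorded in the fold.
#' @export
fractional_cv <- function(n, fractions = c(0.25, 0.5, 0.75, 1.0), reps = 5L,
                          eval_frac = 0.2, mode = c("fixed", "complement"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  if (eval_frac <= 0 || eval_frac >= 1) stop("eval_frac must lie in (0, 1)")
  folds <- list()
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, r)
    n_test <- ceiling(eval_frac * n)
    test <- with_seed(rs, sort(sample.int(n, n_test)))
    rest <- setdiff(seq_len(n), test)
    for (q in fractions) {
      n_train <- ceiling(q * length(rest))
      if (n_train < 1L) stop("training set empty at fraction ", q)
      train <- with_seed(derive_seed(rs, round(1000 * q)),
                         sort(sample(rest, n_train)))
      fold_test <- if (mode == "fixed") test else sort(setdiff(seq_len(n), train))
      folds[[length(folds) + 1L]] <-
        list(train = train, test = fold_test, fraction = q, rep = r)
    }
  }
  new_split_plan(folds, "fractional_cv",
                 list(fractions = fractions, reps = reps,
                      eval_frac = eval_frac, mode = mode, seed = seed),
                 n = n)
}

#' Chronological (forecaster) split on acquisition rounds
#'
#' Train on the past, predict the future: a single fold with train = rows
#' whose round index is < `cut_round` and test = rows with round >=
#' `cut_round`.
#'
#' @param round_index integer vector of per-row acquisition rounds.
#' @param cut_round cut point; both sides must be non-empty.
#' @return a `split_plan` with one fold.
#' @export
chronological_split <- function(round_index, cut_round) {
  if (is.null(round_index)) stop("round_index is required")
  tr <- which(round_index < cut_round)
  te <- which(round_index >= cut_round)
  if (length(tr) == 0L) stop("empty training side: cut_round at or below minimum round")
  if (length(te) == 0L) stop("empty test side: cut_round beyond maximum round")
  new_split_plan(list(list(train = tr, test = te)), "chronological",
                 list(cut_round = cut_round), n = length(round_index))
}

#' Export a split plan as a long-format data frame
#'
#' One row per (fold, role, index); writable as delimited text for external
#' reproduction.
#'
#' @param plan a `split_plan`.
#' @return data.frame with columns `fold`, `role`, `index`.
#' @export
split_plan_table <- function(plan) {
  do.call(rbind, lapply(seq_along(plan$folds), function(j) {
    f <- plan$folds[[j]]
    rbind(
      data.frame(fold = j, role = "train", index = f$train),
      data.frame(fold = j, role = "test", index = f$test)
    )
  }))
}
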