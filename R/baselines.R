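#' Training-mean baseline predictor
#'
#' Predicts the training-fold label mean everywhere; by construction its
#' adjusted R-squared (against that same mean) is exactly 0.
#'
#' @param train_labels non-empty numeric vector.
#' @return function of one argument `n_test` returning a predictive
#'   distribution with constant mean and the training-label variance as its
#'   (constant) predictive variance.
#' @export
mean_baseline <- function(train_labels) {
  if (length(train_labels) == 0L) stop("empty training labels")
  mu <- mean(train_labels)
  v <- if (length(train_labels) > 1L) stats::var(train_labels) else 0
  function(n_test) new_predictive(rep.int(mu, n_test), rep.int(v, n_test))
}

#' Build a single-effect table from observed single mutants
#'
#' Maps each degree-1 substitution seen in the training data to its observed
#' label; duplicate measurements of the same substitution are averaged.
#'
#' @param variants character vector of mutation strings (training side).
#' @param labels matching labels.
#' @return data.frame of class `"single_effect_table"` with columns `pos`,
#'   `mut_aa`, `value`.
#' @export
single_effect_table <- function(variants, labels) {
  stopifnot(length(variants) == length(labels))
  deg1 <- variant_degree(variants) == 1L
  if (!any(deg1)) {
    tab <- data.frame(pos = integer(), mut_aa = character(), value = numeric())
  } else {
    subs <- do.call(rbind, lapply(which(deg1), function(i) {
      s <- parse_mutations(variants[i])
      data.frame(pos = s$pos, mut_aa = s$mut_aa, value = labels[i])
    }))
    tab <- stats::aggregate(value ~ pos + mut_aa, data = subs, FUN = mean)
  }
  class(tab) <- c("single_effect_table", "data.frame")
  tab
}

#' Additive composition baseline for multi-mutants
#'
#' Predicts a degree >= 2 variant as the sum of the observed labels of all of
#' its constituent single substitutions: y(V1:V2) = y(V1) + y(V2), and for
#' higher degrees the sum over all constituents. Returns `NA` when any
#' constituent substitution is absent from the table; callers exclude such
#' variants from metric computation (the count of exclusions is reported by
#' [additive_predict()]).
#'
#' In `"singles"` mode (default) a degree-k variant is the plain sum of its k
#' single-substitution observations. For degree-3 variants, `"decompositions"`
#' mode instead averages y(double) + y(single) over the three ways of
#' splitting the triple into an observed double and a single, using
#' `pair_table` (observed double labels built by [pair_effect_table()]);
#' decompositions whose double is unobserved fall back to the sum of its two
#' singles.
#'
#' @param table a [single_effect_table()].
#' @param variant one mutation string of degree >= 2.
#' @param mode `"singles"` or `"decompositions"` (degree-3 only).
#' @param pair_table optional [pair_effect_table()] for decompositions mode.
#' @return predicted label, or `NA` if a constituent is unobserved.
#' @export
additive_baseline <- function(table, variant,
                              mode = c("singles", "decompositions"),
                              pair_table = NULL) {
  mode <- match.arg(mode)
  subs <- parse_mutations(variant)
  k <- nrow(subs)
  if (k < 2L) stop("additive baseline applies to degree >= 2 variants")
  key <- paste(subs$pos, subs$mut_aa)
  idx <- match(key, paste(table$pos, table$mut_aa))
  if (anyNA(idx)) return(NA_real_)
  singles <- table$value[idx]
  if (mode == "singles" || k != 3L || is.null(pair_table)) {
    return(sum(singles))
  }
  pair_key <- function(a, b) {
    paste(key[a], key[b], sep = "|")
  }
  vals <- vapply(1:3, function(out) {
    inpair <- setdiff(1:3, out)
    pk <- pair_key(inpair[1], inpair[2])
    pv <- pair_table$value[match(pk, pair_table$key)]
    if (is.na(pv)) pv <- singles[inpair[1]] + singles[inpair[2]]
    pv + singles[out]
  }, 0)
  mean(vals)
}

#' Table of observed double-mutant labels keyed by their substitution pair
#'
#' Companion to [single_effect_table()] for the decompositions mode of the
#' additive baseline; duplicate measurements are averaged.
#'
#' @param variants character vector of mutation strings.
#' @param labels matching labels.
#' @return data.frame with columns `key` (`"pos aa|pos aa"`, positions
#'   ascending) and `value`.
#' @export
pair_effect_table <- function(variants, labels) {
  stopifnot(length(variants) == length(labels))
  deg2 <- variant_degree(variants) == 2L
  if (!any(deg2)) return(data.frame(key = character(), value = numeric()))
  rows <- do.call(rbind, lapply(which(deg2), function(i) {
    s <- parse_mutations(variants[i])
    data.frame(key = paste(paste(s$pos, s$mut_aa), collapse = "|"),
               value = labels[i], stringsAsFactors = FALSE)
  }))
  stats::aggregate(value ~ key, data = rows, FUN = mean)
}

#' Vectorized additive baseline with a missing-constituent count
#' @param table a [single_effect_table()].
#' @param variants mutation strings of degree >= 2.
#' @return list with `pred` (numeric, `NA` where incomputable) and
#'   `n_missing`.
#' @export
additive_predict <- function(table, variants) {
  pred <- vapply(variants, function(v) additive_baseline(table, v), 0,
                 USE.NAMES = FALSE)
  n_missing <- sum(is.na(pred))
  if (n_missing > 0L) {
    message("additive baseline: ", n_missing, " of ", length(variants),
            " variants have unobserved constituents and were excluded")
  }
  list(pred = pred, n_missing = n_missing)
}

#' Ranking baseline: order candidates by an external score
#'
#' Sorts candidates descending by the supplied scores (e.g. an unsupervised
#' evolutionary score); ties are broken by the original index, so the order
#' is stable. Used as a selection baseline against Bayesian optimization.
#'
#' @param scores numeric vector aligned to the candidate list.
#' @return integer ordering (candidate indices, best first).
#' @export
ranking_oracle <- function(scores) {
  order(-scores, seq_along(scores))
}
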