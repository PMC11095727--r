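#' Build a synthetic ground-truth fitness landscape
#'
#' The landscape is additive with optional pairwise epistasis: the latent score
#' of a variant is the sum of per-substitution additive effects plus every
#' pairwise epistatic term whose two (site, residue) pairs are both present.
#' The observable fitness is a link function of that score; the
#' `"sigmoid"` link squashes scores into (0, 1) and, combined with
#' predominantly deleterious additive effects, produces the bimodal
#' functional/non-functional label distribution characteristic of deep
#' mutational scans.
#'
#' The additive effect of substituting site i to residue a decomposes as
#' b_i + e_ia: a per-site component b_i ~ Normal(`effect_mean`,
#' `position_effect_sd`^2) shared by every substitution at the site
#' (site conservation: how much the position tolerates any change) and a
#' residue-specific component e_ia ~ Normal(0, `effect_scale`^2). With
#' `position_effect_sd = 0` (the default) effects are i.i.d.
#' Normal(`effect_mean`, `effect_scale`^2) across (site, residue). Effects
#' are exactly zero at the wildtype residue of every site. Epistasis lives on
#' `n_epistatic_pairs` site pairs chosen uniformly at random; an interacting
#' pair carries one Normal(0, `epistasis_scale`^2) term per non-wildtype
#' residue combination, so any variant substituting both sites feels a
#' coupling.
#'
#' @param L sequence length (>= 2).
#' @param n_epistatic_pairs number of pairwise epistatic terms (>= 0).
#' @param effect_scale standard deviation of additive effects (>= 0).
#' @param epistasis_scale standard deviation of epistatic terms (>= 0).
#' @param link `"identity"` or `"sigmoid"` (bimodal functional link).
#' @param assay_noise_sd homoscedastic Gaussian assay noise sd (>= 0).
#' @param seed integer seed; the landscape is deterministic given it.
#' @param effect_mean mean of additive effects; non-positive by default
#'   (most mutations are deleterious).
#' @param position_effect_sd standard deviation of the shared per-site effect
#'   component (default 0: no site-level structure).
#' @param link_threshold,link_steepness sigmoid link parameters: fitness =
#'   1 / (1 + exp(-steepness * (score - threshold))).
#' @param wildtype optional wildtype sequence; random canonical sequence of
#'   length `L` if omitted.
#' @return an object of class `"landscape"`.
#' @export
build_landscape <- function(L, n_epistatic_pairs = 0L, effect_scale = 1,
                            epistasis_scale = 0, link = c("identity", "sigmoid"),
                            assay_noise_sd = 0.1, seed = 1L,
                            effect_mean = -0.5, position_effect_sd = 0,
                            link_threshold = 0, link_steepness = 3,
                            wildtype = NULL) {
  link <- match.arg(link)
  if (!is.numeric(L) || L < 2) stop("L must be an integer >= 2")
  L <- as.integer(L)
  if (effect_scale < 0 || epistasis_scale < 0) stop("scales must be >= 0")
  if (assay_noise_sd < 0) stop("assay_noise_sd must be >= 0")
  if (n_epistatic_pairs < 0) stop("n_epistatic_pairs must be >= 0")
  aas <- aa_alphabet(extended = FALSE)

  with_seed(seed, {
    if (is.null(wildtype)) {
      wildtype <- paste(sample(aas, L, replace = TRUE), collapse = "")
    }
    wt <- strsplit(wildtype, "")[[1L]]
    if (length(wt) != L) stop("wildtype length does not match L")

    site_effect <- stats::rnorm(L, mean = effect_mean, sd = position_effect_sd)
    additive <- site_effect +
      matrix(stats::rnorm(L * 20L, mean = 0, sd = effect_scale),
             nrow = L, ncol = 20L, dimnames = list(NULL, aas))
    additive[cbind(seq_len(L), match(wt, aas))] <- 0

    pairwise <- NULL
    if (n_epistatic_pairs > 0L && epistasis_scale > 0) {
      n_pairs_avail <- choose(L, 2)
      n_take <- min(n_epistatic_pairs, n_pairs_avail)
      pair_idx <- sample.int(n_pairs_avail, n_take)
      combs <- utils::combn(L, 2L)
      sites <- combs[, pair_idx, drop = FALSE]
      # each interacting site pair couples every non-wildtype residue
      # combination, so any double substitution at the two sites feels it
      pairwise <- do.call(rbind, lapply(seq_len(n_take), function(k) {
        i <- sites[1L, k]; j <- sites[2L, k]
        g <- expand.grid(aa_i = setdiff(aas, wt[i]),
                         aa_j = setdiff(aas, wt[j]),
                         stringsAsFactors = FALSE)
        data.frame(i = i, aa_i = g$aa_i, j = j, aa_j = g$aa_j,
                   eps = stats::rnorm(nrow(g), 0, epistasis_scale),
                   stringsAsFactors = FALSE)
      }))
    }

    structure(list(
      wildtype = wildtype, L = L, additive = additive, pairwise = pairwise,
      link = link, link_threshold = link_threshold,
      link_steepness = link_steepness, assay_noise_sd = assay_noise_sd,
      seed = as.integer(seed)
    ), class = "landscape")
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat("Synthetic fitness landscape\n")
  cat("  L =", x$L, " link =", x$link,
      " epistatic pairs =", if (is.null(x$pairwise)) 0L else nrow(x$pairwise),
      " assay noise sd =", x$assay_noise_sd, "\n")
  invisible(x)
}

apply_link <- function(landscape, score) {
  switch(landscape$link,
    identity = score,
    sigmoid = 1 / (1 + exp(-landscape$link_steepness *
                             (score - landscape$link_threshold))),
    stop("unknown link: ", landscape$link)
  )
}

#' Noise-free true fitness of variants under a landscape
#'
#' @param landscape a [build_landscape()] object.
#' @param variants character vector of mutation strings.
#' @return numeric vector of true fitness values (link applied).
#' @export
true_fitness <- function(landscape, variants) {
  validate_variants(variants, landscape$wildtype)
  aas <- aa_alphabet(extended = FALSE)
  pw <- landscape$pairwise
  pw_key_i <- if (!is.null(pw)) paste(pw$i, pw$aa_i)
  pw_key_j <- if (!is.null(pw)) paste(pw$j, pw$aa_j)
  score <- vapply(variants, function(v) {
    subs <- parse_mutations(v)
    s <- 0
    if (nrow(subs)) {
      s <- sum(landscape$additive[cbind(subs$pos, match(subs$mut_aa, aas))])
      if (!is.null(pw) && nrow(subs) >= 2L) {
        key <- paste(subs$pos, subs$mut_aa)
        hit <- pw_key_i %in% key & pw_key_j %in% key
        if (any(hit)) s <- s + sum(pw$eps[hit])
      }
    }
    s
  }, 0, USE.NAMES = FALSE)
  apply_link(landscape, score)
}

#' Enumerate all single mutants of a landscape's wildtype
#'
#' @param landscape a landscape (or any list with `wildtype`).
#' @return character vector of the 19 * L degree-1 mutation strings.
#' @export
enumerate_single_mutants <- function(landscape) {
  wt <- strsplit(landscape$wildtype, "")[[1L]]
  aas <- aa_alphabet(extended = FALSE)
  unlist(lapply(seq_along(wt), function(p) {
    paste0(wt[p], p, setdiff(aas, wt[p]))
  }), use.names = FALSE)
}

#' Number of distinct degree-d variants of a length-L sequence
#' @keywords internal
n_variants_of_degree <- function(L, degree) choose(L, degree) * 19^degree

#' Sample distinct variants of a fixed mutation degree uniformly
#'
#' @param landscape a landscape object.
#' @param degree mutation degree (>= 1).
#' @param n number of distinct variants to draw; must not exceed the
#'   combinatorial count choose(L, degree) * 19^degree.
#' @param seed integer seed.
#' @return character vector of `n` distinct mutation strings.
#' @export
sample_variants <- function(landscape, degree, n, seed = 1L) {
  L <- landscape$L
  stopifnot(degree >= 1L, n >= 1L)
  total <- n_variants_of_degree(L, degree)
  if (n > total) {
    stop("requested ", n, " variants but only ", format(total, scientific = FALSE),
         " distinct degree-", degree, " variants exist")
  }
  wt <- strsplit(landscape$wildtype, "")[[1L]]
  aas <- aa_alphabet(extended = FALSE)

  with_seed(seed, {
    if (n > 0.75 * total && total <= 2e5) {
      # near-exhaustive request: enumerate and subsample
      combs <- utils::combn(L, degree)
      all_v <- unlist(apply(combs, 2L, function(sites) {
        grids <- expand.grid(lapply(sites, function(p) setdiff(aas, wt[p])),
                             stringsAsFactors = FALSE)
        apply(grids, 1L, function(muts) {
          paste(paste0(wt[sites], sites, muts), collapse = ":")
        })
      }))
      return(sample(all_v, n))
    }
    out <- character(0)
    while (length(out) < n) {
      m <- max(n - length(out), 32L)
      batch <- vapply(seq_len(2L * m), function(i) {
        sites <- sort(sample.int(L, degree))
        muts <- vapply(sites, function(p) sample(setdiff(aas, wt[p]), 1L), "")
        paste(paste0(wt[sites], sites, muts), collapse = ":")
      }, "")
      out <- unique(c(out, batch))
    }
    out[seq_len(n)]
  })
}

#' Construct an assay dataset
#' @keywords internal
new_assay_dataset <- function(variants, labels, round_index = NULL,
                              wildtype = NULL) {
  stopifnot(length(variants) == length(labels))
  if (!is.null(round_index)) {
    stopifnot(length(round_index) == length(variants), all(round_index >= 0))
  }
  structure(list(variants = variants, labels = as.numeric(labels),
                 round_index = round_index, wildtype = wildtype),
            class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat("Assay dataset:", length(x$variants), "variants, degrees",
      paste(range(variant_degree(x$variants)), collapse = "-"),
      if (!is.null(x$round_index)) paste0(", rounds 0-", max(x$round_index)) else "",
      "\n")
  invisible(x)
}

#' @export
as.data.frame.assay_dataset <- function(x, ...) {
  df <- data.frame(mutant = x$variants, fitness = x$labels,
                   stringsAsFactors = FALSE)
  if (!is.null(x$round_index)) df$round <- x$round_index
  df
}

#' Assay variants: true fitness plus homoscedastic Gaussian noise
#'
#' @param landscape a landscape object.
#' @param variants character vector of mutation strings.
#' @param seed integer seed; noise is independent across different seeds and
#'   identical for the same seed.
#' @param round_index optional per-variant acquisition round.
#' @return an `assay_dataset`.
#' @export
assay <- function(landscape, variants, seed = 1L, round_index = NULL) {
  truth <- true_fitness(landscape, variants)
  noise <- with_seed(seed, stats::rnorm(length(variants), 0, landscape$assay_noise_sd))
  new_assay_dataset(variants, truth + noise, round_index,
                    wildtype = landscape$wildtype)
}

#' Simulate an iterative, greedily biased acquisition campaign
#'
#' Round 0 assays a random batch of single mutants. Each later round builds a
#' batch where each pick is, with probability `greedy_fraction`, a new variant
#' obtained by adding one random substitution to a randomly chosen member of
#' the current top 10% of observed variants (degree capped at `max_degree`;
#' at the cap an existing substitution is resampled instead), and otherwise a
#' uniformly random variant at the campaign's current frontier degree
#' (current maximum degree + 1, capped). This reproduces the selection bias of
#' real engineering campaigns: with strong greed the per-round mean label
#' drifts upward and mutation degree grows with round, confounding time with
#' fitness.
#'
#' @param landscape a landscape object.
#' @param n_rounds number of acquisition rounds (>= 1).
#' @param batch_size variants assayed per round (>= 1).
#' @param greedy_fraction share of each batch proposed from top performers,
#'   in [0, 1].
#' @param max_degree maximum mutation degree reachable.
#' @param seed integer seed.
#' @return an `assay_dataset` with `round_index` populated (0-based) and
#'   `n_rounds * batch_size` rows.
#' @export
simulate_campaign <- function(landscape, n_rounds, batch_size,
                              greedy_fraction = 0.9, max_degree = 4L,
                              seed = 1L) {
  stopifnot(n_rounds >= 1L, batch_size >= 1L,
            greedy_fraction >= 0, greedy_fraction <= 1, max_degree >= 1L)
  wt <- strsplit(landscape$wildtype, "")[[1L]]
  aas <- aa_alphabet(extended = FALSE)
  L <- landscape$L

  add_substitution <- function(v) {
    subs <- parse_mutations(v)
    if (nrow(subs) < max_degree) {
      free <- setdiff(seq_len(L), subs$pos)
      p <- if (length(free) == 1L) free else sample(free, 1L)
      subs <- rbind(subs, data.frame(wt_aa = wt[p], pos = p,
                                     mut_aa = sample(setdiff(aas, wt[p]), 1L)))
    } else {
      r <- sample.int(nrow(subs), 1L)
      p <- subs$pos[r]
      subs$mut_aa[r] <- sample(setdiff(aas, c(wt[p], subs$mut_aa[r])), 1L)
    }
    format_mutations(subs)
  }

  random_variant <- function(degree) {
    sites <- sort(sample.int(L, degree))
    muts <- vapply(sites, function(p) sample(setdiff(aas, wt[p]), 1L), "")
    paste(paste0(wt[sites], sites, muts), collapse = ":")
  }

  with_seed(seed, {
    all_variants <- character(0)
    all_labels <- numeric(0)
    all_rounds <- integer(0)
    for (r in seq_len(n_rounds) - 1L) {
      if (r == 0L) {
        batch <- sample(enumerate_single_mutants(landscape),
                        min(batch_size, 19L * L))
        while (length(batch) < batch_size) batch <- c(batch, random_variant(1L))
      } else {
        frontier <- min(max(variant_degree(all_variants)) + 1L, max_degree)
        n_top <- max(1L, ceiling(0.1 * length(all_variants)))
        top <- all_variants[order(all_labels, decreasing = TRUE)[seq_len(n_top)]]
        batch <- character(0)
        for (b in seq_len(batch_size)) {
          greedy <- stats::runif(1) < greedy_fraction
          v <- NA_character_
          for (attempt in 1:25) {
            v <- if (greedy) {
              add_substitution(top[sample.int(length(top), 1L)])
            } else {
              random_variant(frontier)
            }
            if (!v %in% c(all_variants, batch)) break
          }
          batch <- c(batch, v)
        }
      }
      truth <- true_fitness(landscape, batch)
      labels <- truth + stats::rnorm(length(batch), 0, landscape$assay_noise_sd)
      all_variants <- c(all_variants, batch)
      all_labels <- c(all_labels, labels)
      all_rounds <- c(all_rounds, rep.int(r, length(batch)))
    }
    new_assay_dataset(all_variants, all_labels, all_rounds,
                      wildtype = landscape$wildtype)
  })
}
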