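test_that("fitness is additive when epistasis is off and the identity link is used", {
  land <- build_landscape(L = 15, n_epistatic_pairs = 0, epistasis_scale = 0,
                          link = "identity", assay_noise_sd = 0, seed = 3)
  expect_identical(true_fitness(land, ""), 0)   # wildtype anchors at link(0)

  doubles <- sample_variants(land, degree = 2, n = 30, seed = 4)
  for (v in doubles) {
    subs <- parse_mutations(v)
    singles <- vapply(seq_len(nrow(subs)), function(i) {
      format_mutations(subs[i, , drop = FALSE])
    }, "")
    expect_equal(true_fitness(land, v), sum(true_fitness(land, singles)),
                 tolerance = 1e-12)
  }
})

test_that("a single pairwise term adds exactly its epistatic effect", {
  wt <- paste(rep("A", 10), collapse = "")
  land <- build_landscape(L = 10, link = "identity", assay_noise_sd = 0,
                          seed = 1, wildtype = wt)
  land$pairwise <- data.frame(i = 3L, aa_i = "K", j = 7L, aa_j = "R",
                              eps = 0.5, stringsAsFactors = FALSE)
  # brute force: the stated sum of additive effects plus the pairwise term
  aas <- aa_alphabet(FALSE)
  expected <- unname(land$additive[3, match("K", aas)] +
                       land$additive[7, match("R", aas)] + 0.5)
  expect_equal(true_fitness(land, "A3K:A7R"), expected, tolerance = 1e-12)
  expect_equal(true_fitness(land, "A3K:A7R") -
                 true_fitness(land, "A3K") - true_fitness(land, "A7R"),
               0.5, tolerance = 1e-12)
  # the term only fires when both (site, residue) pairs are present
  expect_equal(true_fitness(land, "A3K:A7C"),
               unname(land$additive[3, match("K", aas)] +
                        land$additive[7, match("C", aas)]), tolerance = 1e-12)
})

test_that("single-mutant enumeration is complete and valid", {
  expect_length(enumerate_single_mutants(build_landscape(L = 2, seed = 1)), 38)
  land76 <- build_landscape(L = 76, seed = 2)
  sv <- enumerate_single_mutants(land76)
  expect_length(sv, 1444)          # 19 * 76, covers a 1255-variant scan
  expect_false(anyDuplicated(sv) > 0)
  expect_true(all(variant_degree(sv) == 1L))
  expect_silent(validate_variants(sv, land76$wildtype))
})

test_that("variant sampling is uniform-without-replacement and seeded", {
  land <- build_landscape(L = 3, seed = 5)
  # distinct doubles: choose(3,2) * 19^2 = 1083
  all_doubles <- sample_variants(land, 2, 1083, seed = 1)
  expect_length(unique(all_doubles), 1083)
  expect_error(sample_variants(land, 2, 1084, seed = 1), "distinct")

  land2 <- build_landscape(L = 8, seed = 6)
  full <- sample_variants(land2, 1, 19 * 8, seed = 2)
  expect_setequal(full, enumerate_single_mutants(land2))
  expect_identical(sample_variants(land2, 2, 40, seed = 9),
                   sample_variants(land2, 2, 40, seed = 9))
})

test_that("assay noise has the configured scale and seed contract", {
  land <- build_landscape(L = 10, assay_noise_sd = 0, seed = 7,
                          link = "identity")
  v <- sample_variants(land, 1, 50, seed = 1)
  expect_identical(assay(land, v, seed = 3)$labels, true_fitness(land, v))

  land$assay_noise_sd <- 0.3
  truth <- true_fitness(land, v[1])
  draws <- vapply(1:10000, function(s) {
    assay(land, v[1], seed = s)$labels
  }, 0)
  expect_equal(stats::sd(draws - truth), 0.3, tolerance = 0.05 * 0.3 / 0.3)
  expect_identical(assay(land, v, seed = 42)$labels,
                   assay(land, v, seed = 42)$labels)
})

test_that("campaign bookkeeping: size, rounds and determinism", {
  land <- build_landscape(L = 20, seed = 8)
  ds <- simulate_campaign(land, n_rounds = 4, batch_size = 15, seed = 3)
  expect_length(ds$labels, 60)
  expect_identical(sort(unique(ds$round_index)), 0:3)
  ds2 <- simulate_campaign(land, n_rounds = 4, batch_size = 15, seed = 3)
  expect_identical(ds$variants, ds2$variants)
  expect_identical(ds$labels, ds2$labels)
})

test_that("unbiased campaigns show no round-label drift; greedy ones do", {
  # zero-mean effects, identity link, no epistasis: random acquisition at any
  # degree has expectation 0, so per-round means are indistinguishable
  round_means <- sapply(1:20, function(s) {
    land <- build_landscape(L = 20, seed = 100 + s, effect_mean = 0,
                            link = "identity", epistasis_scale = 0,
                            assay_noise_sd = 0.1)
    ds <- simulate_campaign(land, n_rounds = 5, batch_size = 20,
                            greedy_fraction = 0, seed = s)
    tapply(ds$labels, ds$round_index, mean)
  })
  grand <- rowMeans(round_means)
  # each entry averages 20 seeds x 20 picks of sd ~1 effects; se ~ 0.09
  expect_lt(max(grand) - min(grand), 0.35)

  # greedy acquisition on a rugged landscape confounds round with label
  rhos <- sapply(1:10, function(s) {
    land <- build_landscape(L = 20, seed = 200 + s, effect_mean = 0,
                            link = "identity", n_epistatic_pairs = 40,
                            epistasis_scale = 0.5, assay_noise_sd = 0.1)
    ds <- simulate_campaign(land, n_rounds = 6, batch_size = 20,
                            greedy_fraction = 0.9, seed = s)
    spearman_rho(ds$round_index, ds$labels)
  })
  expect_gt(mean(rhos), 0.3)
})

test_that("sigmoid link with deleterious effects collapses function with degree", {
  for (s in 1:5) {
    land <- build_landscape(L = 25, seed = 300 + s, effect_mean = -0.6,
                            effect_scale = 1, link = "sigmoid",
                            assay_noise_sd = 0.05)
    frac_functional <- sapply(1:4, function(d) {
      v <- sample_variants(land, d, 150, seed = 10 * s + d)
      mean(assay(land, v, seed = s)$labels > 0.5)
    })
    expect_true(all(diff(frac_functional) <= 0.05))  # non-increasing (MC slack)
  }
})

test_that("surrogate embeddings are deterministic, finite and additive when linear", {
  land <- build_landscape(L = 12, seed = 9)
  wt <- land$wildtype
  v <- c("", sample_variants(land, 1, 5, seed = 1),
         sample_variants(land, 2, 5, seed = 2))
  E <- surrogate_embedding(c(v, v[3]), wt, d = 16, seed = 4)
  expect_equal(E[3, ], E[nrow(E), ], tolerance = 1e-12)  # same variant, same row
  expect_identical(E, surrogate_embedding(c(v, v[3]), wt, d = 16, seed = 4))
  expect_equal(dim(E), c(length(v) + 1L, 16L))
  expect_true(all(is.finite(E)))

  # linear map: embedding(double) = embedding(wt) + offsets of its singles
  dbl <- v[7]
  subs <- parse_mutations(dbl)
  s1 <- format_mutations(subs[1, , drop = FALSE])
  s2 <- format_mutations(subs[2, , drop = FALSE])
  E2 <- surrogate_embedding(c("", s1, s2, dbl), wt, d = 16, seed = 4)
  expect_equal(E2[4, ], E2[1, ] + (E2[2, ] - E2[1, ]) + (E2[3, ] - E2[1, ]),
               tolerance = 1e-10)
})

test_that("dataset round-trips through CSV and the wildtype through FASTA", {
  land <- build_landscape(L = 10, seed = 10)
  ds <- assay(land, c("", sample_variants(land, 1, 8, seed = 1)), seed = 2,
              round_index = rep(0:2, each = 3))
  csv <- tempfile(fileext = ".csv")
  write_assay_csv(ds, csv)
  back <- read_assay_csv(csv, wildtype = land$wildtype)
  expect_identical(back$variants, ds$variants)
  expect_equal(back$labels, ds$labels, tolerance = 1e-12)
  expect_identical(back$round_index, ds$round_index)

  fa <- tempfile(fileext = ".fasta")
  write_wildtype_fasta(land$wildtype, fa)
  expect_identical(read_wildtype_fasta(fa), land$wildtype)
})
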