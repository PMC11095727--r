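test_that("the benchmark runner is complete, deterministic and failure-tolerant", {
  land <- tiny_landscape(L = 10, seed = 14)
  v <- sample_variants(land, 1, 40, seed = 1)
  ds <- assay(land, v, seed = 2)
  X <- one_hot_encode(ds$variants, land$wildtype)
  E <- surrogate_embedding(ds$variants, land$wildtype, d = 8, seed = 3)
  plans <- list(random = random_cv(40, k = 4, seed = 4))
  res <- run_benchmark(ds$labels, list(one_hot = X, surrogate = E),
                       c("mean", "knn", "gp-lin"), plans,
                       metrics = c("adjusted_r2", "spearman"), seed = 5,
                       optimize_hparams = FALSE)
  # every configured combination appears
  combos <- unique(res$per_fold[, c("representation", "regressor", "metric")])
  expect_identical(nrow(combos), 2L * 3L * 2L)
  expect_identical(nrow(res$per_fold), 2L * 3L * 2L * 4L)
  expect_true(all(c("mean", "se") %in% names(res$aggregate)))

  res2 <- run_benchmark(ds$labels, list(one_hot = X, surrogate = E),
                        c("mean", "knn", "gp-lin"), plans,
                        metrics = c("adjusted_r2", "spearman"), seed = 5,
                        optimize_hparams = FALSE)
  expect_identical(res$per_fold, res2$per_fold)    # end-to-end determinism

  # a degenerate fold (constant training labels) is an NA cell, not a crash
  y_bad <- rep(1, 40)
  resb <- run_benchmark(y_bad, list(one_hot = X), "gp-lin", plans,
                        metrics = "mse", seed = 6)
  expect_true(all(is.na(resb$per_fold$value)))
})

test_that("mean-baseline adjusted R2 aggregates to zero by construction", {
  land <- tiny_landscape(L = 8, seed = 15)
  ds <- assay(land, sample_variants(land, 1, 30, seed = 1), seed = 2)
  X <- one_hot_encode(ds$variants, land$wildtype)
  res <- run_benchmark(ds$labels, list(X = X), "mean",
                       list(cv = random_cv(30, 3, seed = 3)),
                       metrics = "adjusted_r2", seed = 4)
  expect_equal(res$aggregate$mean, 0, tolerance = 1e-12)
})

test_that("selection-bias report contrasts random CV against the forecaster split", {
  land <- build_landscape(L = 18, seed = 16, effect_mean = 0,
                          n_epistatic_pairs = 30, epistasis_scale = 0.5,
                          link = "identity", assay_noise_sd = 0.1)
  rep <- case_selection_bias(land, n_rounds = 5, batch_size = 15,
                             greedy_fraction = 0.9, regressor = "knn",
                             seed = 17)
  expect_true(is.finite(rep$spearman_random))
  expect_true(is.finite(rep$spearman_chronological))
  expect_equal(rep$gap, rep$spearman_random - rep$spearman_chronological)
  expect_true(is.finite(rep$confound_rho))
  expect_error(
    case_selection_bias(build_landscape(L = 6, seed = 1), regressor = "knn",
                        n_rounds = 1, batch_size = 10, seed = 1),
    "cut_round|empty|training"
  )
})

test_that("extrapolation grid flags variance collapse instead of ranking by it", {
  # sigmoid link with strongly deleterious effects: degree-3+ labels are
  # near-constant at the non-functional floor
  land <- build_landscape(L = 20, seed = 18, effect_mean = -2,
                          effect_scale = 1, link = "sigmoid",
                          link_threshold = -1, link_steepness = 3,
                          assay_noise_sd = 0.01)
  v <- c(enumerate_single_mutants(land)[1:120],
         sample_variants(land, 2, 80, seed = 1),
         sample_variants(land, 3, 80, seed = 2))
  ds <- assay(land, v, seed = 3)
  rep <- case_extrapolation(ds$variants, ds$labels, land$wildtype,
                            regressor = "knn", seed = 4)
  expect_true(all(c(2, 3) %in% rep$grid$test_degree))
  expect_true(all(c("additive_mse", "additive_spearman") %in% names(rep$grid)))
  expect_true(any(rep$grid$variance_collapsed[rep$grid$test_degree == 3]))
  expect_true(any(grepl("variance collapsed", rep$flags)))
  # both regimes present for every test degree
  expect_identical(sort(unique(rep$grid$regime)),
                   c("include_equal", "lower_only"))
})

test_that("uncertainty growth: linear-kernel variance rises with degree", {
  land <- tiny_landscape(L = 16, seed = 19)
  prof <- case_uncertainty_growth(land, regressors = c("gp-lin", "knn"),
                                  degrees = 1:3, n_train = 60, n_probe = 25,
                                  seed = 20)
  expect_setequal(unique(prof$regressor), c("gp-lin", "knn"))
  v_lin <- prof$mean_variance[prof$regressor == "gp-lin"]
  expect_true(all(diff(v_lin) > 0))   # one-hot norm grows with degree
})

test_that("no training-side artifact depends on test-fold labels", {
  land <- tiny_landscape(L = 12, seed = 21)
  v <- c(enumerate_single_mutants(land)[1:50],
         sample_variants(land, 2, 20, seed = 1))
  ds <- assay(land, v, seed = 2)
  X <- one_hot_encode(ds$variants, land$wildtype)
  tr <- 1:50; te <- 51:70
  y_corrupt <- ds$labels
  y_corrupt[te] <- y_corrupt[te] + 100    # corrupt every test label

  for (y_use in list(ds$labels, y_corrupt)) {
    std <- fit_standardizer(y_use[tr])
    k <- tune_knn(X[tr, ], y_use[tr], seed = 3)
    tab <- single_effect_table(ds$variants[tr], y_use[tr])
    gp <- fit_regressor("gp-m52", X[tr, ], y_use[tr], seed = 4,
                        n_restarts = 1)
    if (!exists("ref")) {
      ref <- list(std = std, k = k, tab = tab, spec = gp$artifacts$gp_spec)
    } else {
      expect_identical(std, ref$std)
      expect_identical(k, ref$k)
      expect_identical(tab, ref$tab)
      expect_identical(gp$artifacts$gp_spec, ref$spec)
    }
  }
})
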