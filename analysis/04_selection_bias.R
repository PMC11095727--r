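#!/usr/bin/env Rscript
# Acquisition-bias case study: the same campaign data evaluated by random CV
# and by a chronological (train-on-past) split, for greedy and unbiased
# acquisition, 10 simulation seeds each.
# Output: results/selection_bias.csv

library(fitscape)
seed <- 20260920
rows <- list()
for (greedy in c(0.9, 0)) {
  for (s in 1:10) {
    land <- build_landscape(L = 25, seed = seed + 30 + s, effect_mean = 0,
                            effect_scale = 0.5, n_epistatic_pairs = 100,
                            epistasis_scale = 1.5, link = "identity",
                            assay_noise_sd = 0.1)
    r <- case_selection_bias(land, greedy_fraction = greedy,
                             regressor = "gp-m52", seed = seed + 50 + s)
    rows[[length(rows) + 1L]] <- data.frame(
      greedy_fraction = greedy, sim = s,
      spearman_random = r$spearman_random,
      spearman_chronological = r$spearman_chronological,
      gap = r$gap, confound_rho = r$confound_rho)
  }
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/selection_bias.csv", row.names = FALSE)

for (g in c(0.9, 0)) {
  sub <- tab[tab$greedy_fraction == g, ]
  message(sprintf(
    "greedy = %.1f: random-CV rho %.2f, chronological rho %.2f, gap %.2f (confound rho %.2f)",
    g, mean(sub$spearman_random), mean(sub$spearman_chronological),
    mean(sub$gap), mean(sub$confound_rho)))
}
message("\nrandom CV flatters the regressor exactly when acquisition is greedy;")
message("the chronological split is the honest forecaster estimate.")
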