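# Shared fixtures: small landscapes and pools built in code at test time.

tiny_landscape <- function(L = 12L, seed = 7L, ...) {
  build_landscape(L = L, seed = seed, ...)
}

# A landscape whose additive effects are dominated by per-site conservation:
# learnable across residues at a seen site, unlearnable at held-out sites.
site_dominated_landscape <- function(L = 30L, seed = 11L, noise = 0) {
  build_landscape(L = L, seed = seed, assay_noise_sd = noise,
                  effect_mean = -0.5, position_effect_sd = 1,
                  effect_scale = 0.1)
}

# Smooth labelled candidate pool: fitness drawn from a GP prior with a
# squared-exponential kernel over surrogate embeddings of single mutants.
smooth_pool <- function(n = 200L, d = 8L, seed = 5L) {
  land <- build_landscape(L = 30L, seed = seed)
  singles <- enumerate_single_mutants(land)
  pool_v <- fitscape:::with_seed(seed, sample(singles, n))
  X <- surrogate_embedding(pool_v, land$wildtype, d = d, seed = seed + 37L)
  spec <- kernel_spec("squared_exponential", sigma2 = 1,
                      lengthscale = stats::median(stats::dist(X)),
                      noise_variance = 0.01)
  y <- gp_prior_sample(X, spec, seed = seed + 91L)$f
  list(X = X, y = y, variants = pool_v, wildtype = land$wildtype)
}
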