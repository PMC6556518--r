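# Programmatic fixtures shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# Coarse-grid spectra dataset: full trait roster, thinned wavelength grid
# so learner fits stay fast in unit tests.
coarse_dataset <- function(seed = 1, step = 10) {
  traits <- simulate_traits(seed = seed)
  cfg <- spectra_config(wavelength_grid = seq(350, 2500, by = step))
  X <- simulate_spectra(traits, cfg, seed = seed)
  list(traits = traits, X = X,
       y = stats::setNames(traits$vcmax, traits$sample_id),
       config = cfg)
}

# Linear response over correlated informative bands (spectra-like
# structure: 20 informative bands share one latent factor, 40 are noise).
# y = X beta exactly; the response itself is noiseless.
linear_band_dataset <- function(seed = 7, n = 100, p = 60) {
  n_inf <- min(20L, p)
  withr::with_seed(seed, {
    z <- stats::rnorm(n)
    load <- stats::runif(n_inf, 0.5, 1.5)
    X <- matrix(stats::rnorm(n * p, sd = 0.3), n, p)
    X[, seq_len(n_inf)] <- X[, seq_len(n_inf)] + outer(z, load)
    dimnames(X) <- list(paste0("s", seq_len(n)), seq_len(p))
    beta <- c(stats::runif(n_inf, 0.3, 1), rep(0, p - n_inf))
    list(X = X, y = as.numeric(X %*% beta), beta = beta)
  })
}

# Two fast learner specs for protocol-level tests where the learners'
# accuracy is irrelevant.
fast_specs <- function(seed = 1) {
  list(
    LASSO = learner_spec("LASSO", inner_folds = 3L, seed = seed),
    PLS = learner_spec("PLS", grid = list(ncomp = 1:4), inner_folds = 3L,
                       seed = seed + 1L)
  )
}

# Compact, stability-oriented specs for the ablation loops.
ablation_specs <- function(seed = 1) {
  ablation_learner_specs(seed)
}
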