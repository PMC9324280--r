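# Shared synthetic worlds.  All cohorts are generated in code at test
# time; scales are kept small so the default suite stays fast.

# A small, strongly informative cohort for pipeline plumbing tests.
tiny_cohort <- function(seed = 1, n = 60, skew = FALSE) {
  generate_cohort(synthetic_config(
    n_samples = n, n_features = 30, n_informative = 2,
    effect_sizes = c(2, 1.5),
    block_structure = list(c(8, 0.6, 0)),
    replicate_noise_sd = 0.1, skew = skew, seed = seed))
}

# The recovery world stated for the selector acceptance check: 5 planted
# features with d in [1, 2] among 100, n = 400 (200 per class).
recovery_config <- function(seed) {
  synthetic_config(
    n_samples = 200, n_features = 100, n_informative = 5,
    effect_sizes = c(2, 1.75, 1.5, 1.25, 1),
    block_structure = rep(list(c(10, 0.6, 0)), 4),
    replicate_noise_sd = 0.1, seed = seed)
}

# Half-scale version of the package's default stated world (200 features,
# 200 per class): stable strong core plus weak effects thinly spread over
# highly correlated blocks.  Used by the stability experiments to keep
# the suite inside its runtime budget.
stability_config <- function(seed) {
  synthetic_config(
    n_samples = 200, n_features = 200, n_informative = 3,
    effect_sizes = c(1.2, 1.0, 0.7),
    block_structure = list(c(20, 0.85, 0.25), c(20, 0.85, 0.2),
                           c(20, 0.85, 0.2), c(20, 0.85, 0.15),
                           c(20, 0.85, 0.15), c(20, 0.85, 0)),
    replicate_noise_sd = 0.2, seed = seed)
}

# Reduced-scale selector configuration used throughout the suite.
reduced_bbrent <- function(seed = 1, N = 5L, K = 30L, Q = 20L) {
  bbrent_config(N = N, K = K, Q = Q, seed = seed)
}

# A deterministic standardised design + labels for solver-level tests.
toy_design <- function(seed, n = 40, p = 4, beta = c(1.5, -1, rep(0, p - 2))) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y)
}
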