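# Shared fixtures: tiny datasets and models built in code at test time.

# A small multi-site phantom dataset (deterministic).
tiny_dataset <- function(n_sites = 2, per_site_n = 12, size = 16, seed = 1,
                         ...) {
  generate_dataset(study_design(n_sites = n_sites, per_site_n = per_site_n,
                                size = size, seed = seed, ...))
}

# A miniature regression model matching the tiny dataset.
tiny_model <- function(n_domains = 2, input = c(16, 16), feature_dim = 8,
                       seed = 1) {
  build_regression_model(input, n_domains, feature_dim = feature_dim,
                         width_scale = 0.25, hidden = 6, seed = seed)
}

# Random row-stochastic matrix (softmax of Gaussian logits).
random_probs <- function(n, k, seed = 1) {
  with_seed <- unlearnr:::with_seed
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k)
    e <- exp(z - apply(z, 1, max))
    e / rowSums(e)
  })
}

expect_all_finite <- function(x) testthat::expect_true(all(is.finite(x)))
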