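# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# Data whose *sample* correlation matrix is exactly the target R:
# whiten a random matrix to exact identity sample covariance, then colour
# it with chol(R). Used for exact PCA eigenstructure oracles.
make_exact_correlation_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  Z %*% chol(R)
}

equicorrelation_matrix <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}

# Small undisturbed one-factor population with known loadings
make_factor_population <- function(n, loadings, seed = 1) {
  cfg <- sim_config(n_individuals = n, n_tests = length(loadings), seed = seed)
  set.seed(seed)
  g <- draw_true_g(cfg)
  x <- generate_true_scores(g, loadings, cfg)
  list(g = g, x = x, cfg = cfg)
}

# Classical 3-indicator closed-form loadings from a covariance matrix
# (tetrad solution), on the covariance metric with var(g) = 1
tetrad_loadings <- function(S) {
  l1 <- sqrt(S[1, 2] * S[1, 3] / S[2, 3])
  l2 <- sqrt(S[1, 2] * S[2, 3] / S[1, 3])
  l3 <- sqrt(S[1, 3] * S[2, 3] / S[1, 2])
  c(l1, l2, l3)
}
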