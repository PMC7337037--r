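test_that("just-identified three-indicator fit reproduces the tetrad closed form", {
  pop <- make_factor_population(2000, c(0.7, 0.5, 0.6), seed = 13)
  fit <- fit_one_factor(pop$x)
  S <- fit$sample_cov
  expect_true(fit$converged)
  expect_equal(fit$loadings, tetrad_loadings(S), tolerance = 1e-6)
  # the ML solution reproduces S exactly: discrepancy ~ 0
  expect_lt(fit$discrepancy, 1e-9)
  expect_equal(fit$implied_covariance, S, tolerance = 1e-6)
})

test_that("loadings are recovered on large synthetic one-factor samples", {
  true_r <- c(0.3, 0.5, 0.7, 0.9, 0.4, 0.6)
  pop <- make_factor_population(100000, true_r, seed = 19)
  fit <- fit_one_factor(pop$x)
  expect_true(fit$converged)
  est_r <- fit$loadings / sqrt(diag(fit$implied_covariance))
  expect_true(all(abs(est_r - true_r) < 0.02))
  th_r <- fit$residual_variances / diag(fit$implied_covariance)
  expect_true(all(abs(th_r - (1 - true_r^2)) < 0.03))
})

test_that("the one-factor fit is invariant to column reordering", {
  pop <- make_factor_population(3000, c(0.4, 0.6, 0.8, 0.5, 0.7), seed = 23)
  fit <- fit_one_factor(pop$x)
  perm <- c(3, 1, 5, 2, 4)
  fit_p <- fit_one_factor(pop$x[, perm])
  expect_equal(fit_p$loadings, fit$loadings[perm], tolerance = 1e-5)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("degenerate score matrices are rejected", {
  x <- matrix(rnorm(200), 50, 4)
  expect_error(fit_one_factor(cbind(x, 1)), "zero-variance")
  expect_error(fit_one_factor(x[, 1:2]), "3 indicators")
  expect_error(fit_one_factor(x[1:3, ]), "more rows")
  expect_error(fit_linear_plus_quadratic(x[, 1:3]), "4 indicators")
})

test_that("the quadratic loadings are a hard elementwise-square constraint", {
  pop <- simulate_population(sim_config(n_individuals = 2000,
                                        disturbance_shape = "negative",
                                        seed = 29))
  fit <- fit_linear_plus_quadratic(pop$observed_scores)
  expect_identical(fit$loading_matrix[, 2], fit$loading_matrix[, 1]^2)
  expect_identical(fit$n_free_params - 2L, 2L * 15L)
  expect_equal(fit$latent_cov[1, 1], 1)
  expect_equal(fit$latent_cov[1, 2], fit$quad_covariance)
  expect_equal(fit$latent_cov[2, 2], fit$quad_variance)
  # implied covariance assembles from the constrained structure
  expect_equal(fit$implied_covariance,
               fit$loading_matrix %*% fit$latent_cov %*% t(fit$loading_matrix) +
                 diag(fit$residual_variances),
               tolerance = 1e-10)
})

test_that("the quadratic model nests the linear model", {
  for (shape in c("none", "negative", "positive")) {
    pop <- simulate_population(sim_config(n_individuals = 1500,
                                          disturbance_shape = shape,
                                          seed = 37 + match(shape, c("none", "negative", "positive"))))
    f1 <- fit_one_factor(pop$observed_scores)
    f2 <- fit_linear_plus_quadratic(pop$observed_scores, start = f1)
    expect_gte(f2$loglik - f1$loglik, -1e-4)
  }
})

test_that("the likelihood-ratio test counts two extra parameters", {
  pop <- simulate_population(sim_config(n_individuals = 1500, seed = 41))
  f1 <- fit_one_factor(pop$observed_scores)
  f2 <- fit_linear_plus_quadratic(pop$observed_scores, start = f1)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_identical(lrt$df, 2L)
  expect_gte(lrt$delta_chi2, 0)
  expect_true(lrt$p >= 0 && lrt$p <= 1)

  # identical log-likelihoods: delta 0, p = 1
  f_same <- f1
  lrt0 <- likelihood_ratio_test(f1, structure(
    modifyList(unclass(f1), list(n_free_params = f1$n_free_params + 2L)),
    class = "slodr_cfa"))
  expect_equal(lrt0$delta_chi2, 0)
  expect_equal(lrt0$p, 1)

  # a full model fitting clearly worse signals optimizer failure
  f_bad <- structure(
    modifyList(unclass(f1), list(n_free_params = f1$n_free_params + 2L,
                                 loglik = f1$loglik - 10)),
    class = "slodr_cfa")
  expect_error(likelihood_ratio_test(f1, f_bad), "optimizer failure")
  expect_error(likelihood_ratio_test(f1, f1), "more free parameters")
})

test_that("a planted quadratic latent effect is detected by the LRT", {
  # explicit g^2 term in every test score; the coefficient must be large
  # enough that the lambda^2 off-diagonal pattern is not absorbable by
  # reshaping the single factor's loadings
  set.seed(53)
  n <- 10000
  g <- rnorm(n)
  k <- 12
  lam <- seq(0.2, 0.9, length.out = k)
  x <- sapply(1:k, function(i)
    lam[i] * g + 0.5 * lam[i]^2 * (g^2 - 1) + sqrt(1 - lam[i]^2) * rnorm(n))
  f1 <- fit_one_factor(x)
  f2 <- fit_linear_plus_quadratic(x, start = f1)
  lrt <- likelihood_ratio_test(f1, f2)
  expect_lt(lrt$p, 0.001)
  expect_gt(f2$quad_variance, 0)
})
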