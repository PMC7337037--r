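test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(n_individuals = 0), "positive integer")
  expect_error(sim_config(n_tests = 2), "at least|>= 3")
  expect_error(sim_config(loading_low = 0.9, loading_high = 0.2), "loading_low")
  expect_error(sim_config(selection_loading = 1.5), "selection_loading")
  expect_error(sim_config(score_sd = 0), "positive")
  expect_error(sim_config(beta_params = list(negative = c(9, -1),
                                             normal = c(9, 9),
                                             positive = c(1, 9))),
               "positive")
})

test_that("true g is normal on the IQ metric and reproducible", {
  cfg <- sim_config(n_individuals = 10000, seed = 101)
  set.seed(cfg$seed)
  g <- draw_true_g(cfg)
  expect_length(g, 10000)
  expect_lt(abs(mean(g) - 100), 0.6)
  expect_lt(abs(sd(g) - 15), 0.4)
  set.seed(cfg$seed)
  expect_identical(draw_true_g(cfg), g)
})

test_that("loadings are uniform in range with the selection override", {
  cfg <- sim_config(seed = 5)
  set.seed(5)
  r <- draw_loadings(cfg)
  expect_length(r, 15)
  expect_true(all(r >= 0.2 & r <= 0.9))
  cfg2 <- sim_config(selection_loading = 0.5, seed = 5)
  set.seed(5)
  r2 <- draw_loadings(cfg2)
  expect_identical(r2[1], 0.5)
  expect_identical(r2[-1], r[-1])
})

test_that("test scores carry the specified population correlation with g", {
  cfg <- sim_config(n_individuals = 100000, n_tests = 3, seed = 7)
  set.seed(7)
  g <- draw_true_g(cfg)
  x <- generate_true_scores(g, c(0.5, 0.3, 0.8), cfg)
  expect_lt(abs(cor(x[, 1], g) - 0.5), 0.01)
  # single-common-factor algebra: corr(x_i, x_j) = r_i r_j
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.5 * 0.3), 0.015)
  expect_lt(abs(cor(x[, 1], x[, 3]) - 0.5 * 0.8), 0.015)
  expect_lt(abs(cor(x[, 2], x[, 3]) - 0.3 * 0.8), 0.015)
  # population metric
  expect_lt(abs(mean(x[, 1]) - 100), 0.3)
  expect_lt(abs(sd(x[, 1]) - 15), 0.2)
})

test_that("a unit loading makes the score an affine copy of g", {
  cfg <- sim_config(n_individuals = 500, n_tests = 3, seed = 3)
  set.seed(3)
  g <- draw_true_g(cfg)
  x <- generate_true_scores(g, c(1, 0.5, 0.5), cfg)
  expect_equal(cor(x[, 1], g), 1)
  expect_error(generate_true_scores(g, c(1.2, 0.5, 0.5), cfg), "\\[-1, 1\\]")
})

test_that("disturbance draws match closed-form beta moments", {
  cfg <- sim_config(n_individuals = 100000, disturbance_shape = "negative",
                    seed = 11)
  set.seed(11)
  d <- draw_disturbance(cfg)
  expect_true(all(d >= 0 & d <= 1))
  expect_lt(abs(mean(d) - 9 / 10), 0.005)
  # closed-form beta skewness 2(b-a)sqrt(a+b+1) / ((a+b+2)sqrt(ab))
  beta_skew <- function(a, b) 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  expect_equal(beta_skew(9, 1), -1.4740554, tolerance = 1e-6)
  expect_lt(abs(skewness_test(d)$skew - beta_skew(9, 1)), 0.05)

  cfgn <- sim_config(n_individuals = 100000, disturbance_shape = "normal",
                     seed = 12)
  set.seed(12)
  dn <- draw_disturbance(cfgn)
  expect_lt(abs(skewness_test(dn)$skew), 0.05)

  expect_error(draw_disturbance(sim_config(disturbance_shape = "none")),
               "none")
})

test_that("disturbance multiplies scores and attenuates correlations with g", {
  x <- matrix(rnorm(50 * 4, 100, 15), 50, 4)
  expect_identical(apply_disturbance(x, rep(1, 50)), x)
  xc <- apply_disturbance(x, rep(0.5, 50))
  expect_equal(cor(xc), cor(x))
  expect_error(apply_disturbance(x, rep(2, 50)), "\\[0, 1\\]")
  expect_error(apply_disturbance(x, rep(0.5, 49)), "match")

  pop <- simulate_population(sim_config(n_individuals = 10000,
                                        disturbance_shape = "negative",
                                        seed = 21))
  r_true <- cor(pop$true_scores, pop$true_g)
  r_obs <- cor(pop$observed_scores, pop$true_g)
  expect_true(all(r_obs < r_true))
})

test_that("simulate_population is complete, consistent and reproducible", {
  cfg <- sim_config(n_individuals = 1000, disturbance_shape = "negative",
                    seed = 31)
  pop <- simulate_population(cfg)
  expect_identical(dim(pop$observed_scores), c(1000L, 15L))
  expect_length(pop$disturbance, 1000)
  expect_equal(pop$observed_scores, pop$true_scores * pop$disturbance)

  pop2 <- simulate_population(cfg)
  expect_identical(pop, pop2)

  pop_clean <- simulate_population(sim_config(n_individuals = 300, seed = 31))
  expect_identical(pop_clean$observed_scores, pop_clean$true_scores)
  expect_null(pop_clean$disturbance)

  df <- as.data.frame(pop)
  expect_identical(dim(df), c(1000L, 17L))
})

test_that("derived replicate seeds are deterministic, distinct and in range", {
  s <- vapply(0:999, function(i) derive_seed(42, i), 1L)
  expect_identical(s, vapply(0:999, function(i) derive_seed(42, i), 1L))
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_false(derive_seed(42, 1) == derive_seed(43, 1))
})
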