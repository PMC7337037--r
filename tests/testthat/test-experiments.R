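test_that("a single-replicate experiment gives well-defined 0/1 proportions", {
  tab <- run_contemporary_experiment(1, conditions = c("none", "negative"),
                                     config_base = sim_config(n_individuals = 1200,
                                                              seed = 7))
  expect_true(all(tab$proportions %in% c(0, 1)))
  expect_identical(colnames(tab$proportions), c("No", "Negative"))
  expect_identical(nrow(tab$replicates), 2L)
})

test_that("experiment tables satisfy their internal consistency invariants", {
  tab <- run_contemporary_experiment(4, conditions = c("negative", "normal"),
                                     config_base = sim_config(n_individuals = 1500,
                                                              seed = 13))
  p <- tab$proportions
  expect_true(all(p >= 0 & p <= 1))
  # skew directions are mutually exclusive per replicate
  expect_true(all(p["positive_skew", ] + p["negative_skew", ] <= 1))
  # the conjunction can never exceed any of its crucial components
  crucial <- c("negative_skew", "res_corr_pos", "quad_significant", "g_g2_corr_neg")
  for (j in colnames(p))
    expect_lte(p["all_crucial", j], min(p[crucial, j]))
})

test_that("experiments are reproducible from the master seed", {
  base <- sim_config(n_individuals = 1000, seed = 314)
  t1 <- run_contemporary_experiment(2, conditions = "negative", config_base = base)
  t2 <- run_contemporary_experiment(2, conditions = "negative", config_base = base)
  expect_identical(t1$proportions, t2$proportions)
  expect_identical(t1$replicates, t2$replicates)

  f1 <- run_traditional_experiment(2, selection_loadings = 0.5,
                                   conditions = "negative", config_base = base)
  f2 <- run_traditional_experiment(2, selection_loadings = 0.5,
                                   conditions = "negative", config_base = base)
  expect_identical(f1$subgroups, f2$subgroups)
})

test_that("the traditional experiment covers the full design grid", {
  fig <- run_traditional_experiment(2, selection_loadings = c(0.1, 0.9),
                                    conditions = c("none", "negative"),
                                    config_base = sim_config(n_individuals = 2000,
                                                             seed = 17))
  expect_identical(nrow(fig$trends), 2L * 2L * 2L)
  expect_identical(nrow(fig$subgroups), 2L * 2L * 2L * 10L)
  expect_true(all(c("selection_loading", "condition", "replicate",
                    "trend_spearman") %in% names(fig$trends)))
  expect_true(all(fig$subgroups$explained_variance > 0 &
                    fig$subgroups$explained_variance <= 1))
})

test_that("the single-run illustration reports the documented statistics", {
  ill <- illustrate_single_run(sim_config(n_individuals = 3000,
                                          disturbance_shape = "negative",
                                          seed = 23))
  expect_s3_class(ill, "slodr_illustration")
  expect_true(is.finite(ill$quad_B) && is.finite(ill$quad_p))
  expect_true(abs(ill$true_g_skew$skew) < 0.2)
  expect_error(illustrate_single_run(sim_config(disturbance_shape = "normal")),
               "negatively skewed")
})

test_that("results round-trip through CSV and JSON with provenance", {
  tab <- run_contemporary_experiment(2, conditions = "negative",
                                     config_base = sim_config(n_individuals = 1000,
                                                              seed = 29))
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_results(tab, path, format = fmt)
    back <- read_results(path)
    expect_equal(back$meta$seed, 29)
    expect_equal(back$meta$n_reps, 2)
    expect_equal(back$results$Negative,
                 unname(tab$proportions[, "Negative"]))
    unlink(path)
  }
  df <- data.frame(a = 1:3, b = c("x", "y", "z"))
  path <- tempfile(fileext = ".csv")
  write_results(df, path, format = "csv")
  expect_equal(read_results(path)$results, df)
  unlink(path)
  expect_error(write_results(tab, tempfile(), format = "yaml"), "arg")
  expect_error(write_results(1:5, tempfile(), format = "csv"), "serialise")
})
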