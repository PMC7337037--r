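# Experiment drivers: replicate-level orchestration over the four
# disturbance conditions, with per-replicate seeds derived from one master
# seed (see derive_seed) so any replicate can be re-run in isolation.

condition_levels <- c("none", "negative", "normal", "positive")
condition_labels <- c(none = "No", negative = "Negative",
                      normal = "Normal", positive = "Positive")
criterion_rows <- c("positive_skew", "negative_skew",
                    "res_corr_pos", "res_corr_neg",
                    "quad_significant", "g_g2_corr_pos", "g_g2_corr_neg",
                    "all_crucial")

#' Criterion-fulfillment proportions across disturbance conditions
#'
#' Runs `n_reps` independent simulated populations per disturbance condition
#' (15 one-factor tests, no selection variable), evaluates the contemporary
#' SLODR criteria on each, and tabulates the proportion of replicates
#' fulfilling each criterion — the simulation analogue of a criterion
#' fulfillment table with one column per disturbance condition.
#'
#' @param n_reps Replicates per condition.
#' @param conditions Character vector of disturbance conditions to run
#'   (subset of `"none"`, `"negative"`, `"normal"`, `"positive"`).
#' @param config_base A [sim_config()] supplying N, the number of tests, and
#'   the score metric; its seed is the master seed and its
#'   `selection_loading` is ignored (forced to `NULL`).
#' @param verbose Print one progress line per condition.
#' @return Object of class `slodr_table`: `proportions` (criterion x
#'   condition matrix), `replicates` (one-row-per-replicate data.frame of the
#'   raw flags and statistics), and metadata (`n_reps`, `n`, `seed`,
#'   non-convergence counts).
#' @examples
#' \donttest{
#' tab <- run_contemporary_experiment(5, conditions = "negative",
#'                                    config_base = sim_config(n_individuals = 1000, seed = 2))
#' tab$proportions
#' }
#' @export
run_contemporary_experiment <- function(n_reps,
                                        conditions = condition_levels,
                                        config_base = sim_config(),
                                        verbose = FALSE) {
  stopifnot(n_reps >= 1)
  conditions <- match.arg(conditions, condition_levels, several.ok = TRUE)
  reps <- list()
  for (cond in conditions) {
    ci <- match(cond, condition_levels)
    if (verbose)
      message(sprintf("condition %s: %d replicates of N = %d",
                      cond, n_reps, config_base$n_individuals))
    for (r in seq_len(n_reps)) {
      cfg <- sim_config(n_individuals = config_base$n_individuals,
                        n_tests = config_base$n_tests,
                        score_mean = config_base$score_mean,
                        score_sd = config_base$score_sd,
                        loading_low = config_base$loading_low,
                        loading_high = config_base$loading_high,
                        selection_loading = NULL,
                        disturbance_shape = cond,
                        beta_params = config_base$beta_params,
                        seed = derive_seed(config_base$seed, (ci - 1) * 1e6 + r))
      pop <- simulate_population(cfg)
      cr <- evaluate_slodr_criteria(pop$observed_scores)
      reps[[length(reps) + 1L]] <- data.frame(
        condition = cond, replicate = r, seed = cfg$seed,
        converged = cr$converged, converged_quad = cr$converged_quad,
        skew_value = cr$skew_value, skew_p = cr$skew_p,
        res_corr = cr$res_corr, res_corr_p = cr$res_corr_p,
        quad_lrt_chi2 = cr$quad_lrt_chi2, quad_lrt_p = cr$quad_lrt_p,
        g_g2_corr = cr$g_g2_corr, g_g2_corr_p = cr$g_g2_corr_p,
        positive_skew = cr$positively_skewed_g,
        negative_skew = cr$negatively_skewed_g,
        res_corr_pos = cr$positive_res_corr,
        res_corr_neg = cr$negative_res_corr,
        quad_significant = cr$significant_quadratic,
        g_g2_corr_pos = cr$positive_g_g2_corr,
        g_g2_corr_neg = cr$negative_g_g2_corr,
        all_crucial = cr$all_crucial)
    }
  }
  reps <- do.call(rbind, reps)
  prop <- sapply(conditions, function(cond) {
    sub <- reps[reps$condition == cond, criterion_rows]
    colMeans(sub)
  })
  prop <- matrix(prop, nrow = length(criterion_rows),
                 dimnames = list(criterion_rows,
                                 unname(condition_labels[conditions])))
  structure(list(proportions = prop,
                 replicates = reps,
                 n_reps = n_reps,
                 n = config_base$n_individuals,
                 seed = config_base$seed,
                 n_nonconverged = sum(!reps$converged | !reps$converged_quad)),
            class = "slodr_table")
}

#' @export
print.slodr_table <- function(x, ...) {
  cat(sprintf("<slodr_table> %d replicates per condition, N = %d, master seed %d\n",
              x$n_reps, x$n, x$seed))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d replicate(s) with a non-converged fit (counted as unfulfilled)\n",
                x$n_nonconverged))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Traditional-paradigm experiment over conditions and selection loadings
#'
#' Repeats [traditional_replicate()] for every combination of selection
#' loading and disturbance condition: per replicate, ten overlapping ability
#' subgroups on the rescaled selection variable and the first-PC explained
#' variance of the 14 remaining tests in each. The per-replicate Spearman
#' rank correlation between subgroup mean and explained variance summarises
#' the trend the differentiation hypothesis predicts to be negative.
#'
#' @param n_reps Replicates per cell (default 20).
#' @param selection_loadings Population correlations between the selection
#'   variable and g (default 0.1, 0.5, 0.9).
#' @param conditions Disturbance conditions (default all four).
#' @param config_base A [sim_config()] giving N and the master seed.
#' @param verbose Print one progress line per cell.
#' @return Object of class `slodr_saturation`: `subgroups` (tidy data.frame, one
#'   row per subgroup x replicate x cell) and `trends` (one row per replicate
#'   x cell with the Spearman trend), plus metadata.
#' @export
run_traditional_experiment <- function(n_reps = 20,
                                       selection_loadings = c(0.1, 0.5, 0.9),
                                       conditions = condition_levels,
                                       config_base = sim_config(),
                                       verbose = FALSE) {
  conditions <- match.arg(conditions, condition_levels, several.ok = TRUE)
  sub_rows <- list(); trend_rows <- list()
  for (li in seq_along(selection_loadings)) {
    for (cond in conditions) {
      ci <- match(cond, condition_levels)
      if (verbose)
        message(sprintf("selection loading %.1f, condition %s",
                        selection_loadings[li], cond))
      for (r in seq_len(n_reps)) {
        cfg <- sim_config(n_individuals = config_base$n_individuals,
                          n_tests = config_base$n_tests,
                          score_mean = config_base$score_mean,
                          score_sd = config_base$score_sd,
                          loading_low = config_base$loading_low,
                          loading_high = config_base$loading_high,
                          selection_loading = selection_loadings[li],
                          disturbance_shape = cond,
                          beta_params = config_base$beta_params,
                          seed = derive_seed(config_base$seed,
                                             li * 1e7 + (ci - 1) * 1e6 + r))
        tr <- traditional_replicate(cfg)
        sg <- tr$subgroups
        sg$selection_loading <- selection_loadings[li]
        sg$condition <- cond
        sg$replicate <- r
        sub_rows[[length(sub_rows) + 1L]] <- sg
        trend_rows[[length(trend_rows) + 1L]] <-
          data.frame(selection_loading = selection_loadings[li],
                     condition = cond, replicate = r, seed = cfg$seed,
                     trend_spearman = tr$trend_spearman,
                     mean_explained_variance = mean(sg$explained_variance))
      }
    }
  }
  structure(list(subgroups = do.call(rbind, sub_rows),
                 trends = do.call(rbind, trend_rows),
                 n_reps = n_reps,
                 n = config_base$n_individuals,
                 seed = config_base$seed),
            class = "slodr_saturation")
}

#' @export
print.slodr_saturation <- function(x, ...) {
  cat(sprintf("<slodr_saturation> %d replicates per cell, N = %d, master seed %d\n",
              x$n_reps, x$n, x$seed))
  agg <- stats::aggregate(trend_spearman ~ selection_loading + condition,
                          data = x$trends, FUN = stats::median)
  names(agg)[3] <- "median_trend"
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Single-run illustration of negatively skewed disturbance
#'
#' One simulated population under negatively skewed disturbance, reported the
#' way a worked single-run example is usually shown: skewness (with p) of the
#' true latent trait and of estimated g, the correlation of estimated g with
#' log individual residual variance, and an ordinary least-squares regression
#' of one observed test score on estimated g and its square (the quadratic
#' coefficient picks up the bend that disturbance induces).
#'
#' @param config A [sim_config()] with `disturbance_shape = "negative"`.
#' @param test_index Which observed test to use for the quadratic OLS
#'   (default 1).
#' @return Object of class `slodr_illustration`: `true_g_skew`, `g_hat_skew`
#'   (both [skewness_test()] results), `res_corr` ([correlation_with_p()]
#'   result), `quad_B`, `quad_p`, `linear_B`, and the pieces needed to plot
#'   (`g_hat`, observed test scores, fitted curves).
#' @export
illustrate_single_run <- function(config = sim_config(disturbance_shape = "negative"),
                                  test_index = 1) {
  stopifnot(inherits(config, "slodr_config"))
  if (config$disturbance_shape != "negative")
    stop("the illustration is defined for negatively skewed disturbance", call. = FALSE)
  pop <- simulate_population(config)
  fit <- fit_one_factor(pop$observed_scores)
  g_hat <- predict_factor_scores(fit, pop$observed_scores)$g_hat
  lrv <- individual_log_residual_variance(fit, pop$observed_scores, g_hat)
  y <- pop$observed_scores[, test_index]
  qfit <- stats::lm(y ~ g_hat + I(g_hat^2))
  sm <- summary(qfit)$coefficients
  structure(list(true_g_skew = skewness_test(pop$true_g),
                 g_hat_skew = skewness_test(g_hat),
                 res_corr = correlation_with_p(g_hat, lrv),
                 linear_B = sm["g_hat", "Estimate"],
                 quad_B = sm["I(g_hat^2)", "Estimate"],
                 quad_p = sm["I(g_hat^2)", "Pr(>|t|)"],
                 g_hat = g_hat,
                 test_scores = y,
                 test_index = test_index,
                 population = pop),
            class = "slodr_illustration")
}

#' @export
print.slodr_illustration <- function(x, ...) {
  cat("<slodr_illustration> one run, negatively skewed disturbance\n")
  cat(sprintf("  skew(true g)      = %+.3f (p = %.3g)\n",
              x$true_g_skew$skew, x$true_g_skew$p))
  cat(sprintf("  skew(estimated g) = %+.3f (p = %.3g)\n",
              x$g_hat_skew$skew, x$g_hat_skew$p))
  cat(sprintf("  r(g, log res. var.) = %.3f (p = %.3g)\n",
              x$res_corr$r, x$res_corr$p))
  cat(sprintf("  OLS on test %d: linear B = %.3f, quadratic B = %.3f (p = %.3g)\n",
              x$test_index, x$linear_B, x$quad_B, x$quad_p))
  invisible(x)
}
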