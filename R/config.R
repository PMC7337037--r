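#' Simulation configuration
#'
#' Bundles every generative parameter of one simulated population: the number
#' of virtual participants and tests, the IQ metric of the latent trait, the
#' range of the uniform distribution the population test-g correlations are
#' drawn from, an optional fixed correlation for the first test (the
#' "selection variable" of the traditional subgroup paradigm), the shape of
#' the multiplicative disturbance variable, and the RNG seed.
#'
#' The disturbance variable is a per-person value in \[0, 1\] drawn from a
#' beta distribution; every test score is multiplied by it, so lower values
#' mean stronger disturbance. The three stock shapes are negatively skewed
#' Beta(9, 1) (most people near 1, a few strongly disturbed), approximately
#' normal Beta(9, 9), and positively skewed Beta(1, 9); `"none"` disables
#' disturbance entirely.
#'
#' @param n_individuals Number of virtual participants (default 10000).
#' @param n_tests Number of test scores per participant (default 15; at least
#'   3 so a one-factor model is identified).
#' @param score_mean,score_sd Population mean and SD of the latent trait and
#'   of every undisturbed test score (default 100 and 15, the IQ metric).
#' @param loading_low,loading_high Bounds of the uniform distribution the
#'   population test-g correlations are drawn from (default 0.2 and 0.9).
#' @param selection_loading Optional fixed population correlation between the
#'   first test (the selection variable) and g, conventionally 0.1, 0.5 or
#'   0.9. `NULL` (default) leaves all loadings uniform draws.
#' @param disturbance_shape One of `"none"`, `"negative"`, `"normal"`,
#'   `"positive"`.
#' @param beta_params Named list mapping the three disturbance shapes to
#'   `c(alpha, beta)` parameter pairs. Rarely changed.
#' @param seed Integer RNG seed; the same config reproduces the same
#'   population bit for bit.
#'
#' @return An object of class `slodr_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 500, disturbance_shape = "negative", seed = 1)
#' cfg$beta_params$negative
#' @export
sim_config <- function(n_individuals = 10000,
                       n_tests = 15,
                       score_mean = 100,
                       score_sd = 15,
                       loading_low = 0.2,
                       loading_high = 0.9,
                       selection_loading = NULL,
                       disturbance_shape = c("none", "negative", "normal", "positive"),
                       beta_params = list(negative = c(9, 1),
                                          normal   = c(9, 9),
                                          positive = c(1, 9)),
                       seed = 1L) {
  disturbance_shape <- match.arg(disturbance_shape)
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      is.na(n_individuals) || n_individuals < 1 || n_individuals != round(n_individuals))
    stop("`n_individuals` must be a positive integer", call. = FALSE)
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 3 ||
      n_tests != round(n_tests))
    stop("`n_tests` must be an integer >= 3 (one-factor identification)", call. = FALSE)
  if (score_sd <= 0) stop("`score_sd` must be positive", call. = FALSE)
  if (!(loading_low > 0 && loading_high < 1 && loading_low < loading_high))
    stop("need 0 < loading_low < loading_high < 1", call. = FALSE)
  if (!is.null(selection_loading)) {
    if (!is.numeric(selection_loading) || length(selection_loading) != 1L ||
        selection_loading <= 0 || selection_loading >= 1)
      stop("`selection_loading` must be a single value in (0, 1)", call. = FALSE)
  }
  stopifnot(all(c("negative", "normal", "positive") %in% names(beta_params)))
  for (bp in beta_params)
    if (length(bp) != 2L || any(bp <= 0))
      stop("beta parameters must be pairs of positive values", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)

  structure(list(n_individuals = as.integer(n_individuals),
                 n_tests = as.integer(n_tests),
                 score_mean = score_mean,
                 score_sd = score_sd,
                 loading_low = loading_low,
                 loading_high = loading_high,
                 selection_loading = selection_loading,
                 disturbance_shape = disturbance_shape,
                 beta_params = beta_params,
                 seed = as.integer(seed)),
            class = "slodr_config")
}

#' @export
print.slodr_config <- function(x, ...) {
  cat("<slodr_config>\n")
  cat(sprintf("  N = %d participants, %d tests (M = %g, SD = %g)\n",
              x$n_individuals, x$n_tests, x$score_mean, x$score_sd))
  cat(sprintf("  loadings ~ Uniform(%g, %g)%s\n", x$loading_low, x$loading_high,
              if (is.null(x$selection_loading)) ""
              else sprintf(", selection variable fixed at %g", x$selection_loading)))
  if (x$disturbance_shape == "none") {
    cat("  disturbance: none\n")
  } else {
    bp <- x$beta_params[[x$disturbance_shape]]
    cat(sprintf("  disturbance: %s skew, Beta(%g, %g)\n",
                x$disturbance_shape, bp[1], bp[2]))
  }
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Derive a replicate seed from a master seed
#'
#' Deterministic counter-based split of one master seed into per-replicate
#' substreams, so that replicate `i` of an experiment is individually
#' re-runnable and independent of how many replicates run before it. The
#' derived seed is `((seed * 48271 + counter) * 69621) mod (2^31 - 1)`,
#' a fixed full-period affine map kept inside the 32-bit integer range
#' (intermediate products stay below 2^53, so the double arithmetic is exact).
#'
#' @param seed Master integer seed.
#' @param counter Non-negative replicate counter.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647
  s <- ((as.double(seed) %% m) * 48271) %% m
  s <- (s + as.double(counter)) %% m
  as.integer((s * 69621) %% m) + 1L
}
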