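#' Draw the true latent trait
#'
#' Allocates each virtual participant a true g score from a normal
#' distribution on the IQ metric (by default M = 100, SD = 15).
#'
#' @param config A [sim_config()] object.
#' @return Numeric vector of length `n_individuals`.
#' @export
draw_true_g <- function(config) {
  stopifnot(inherits(config, "slodr_config"))
  if (config$n_individuals < 2)
    stop("need at least 2 individuals", call. = FALSE)
  stats::rnorm(config$n_individuals, mean = config$score_mean, sd = config$score_sd)
}

#' Draw population test-g correlations
#'
#' Draws one population correlation (loading, on the correlation metric) per
#' test from Uniform(`loading_low`, `loading_high`). When the config fixes a
#' `selection_loading`, the first test's correlation is overwritten with it:
#' that test is the selection variable of the traditional subgroup paradigm.
#'
#' @param config A [sim_config()] object.
#' @return Numeric vector of length `n_tests`, all values in (0, 1).
#' @export
draw_loadings <- function(config) {
  stopifnot(inherits(config, "slodr_config"))
  r <- stats::runif(config$n_tests, config$loading_low, config$loading_high)
  if (!is.null(config$selection_loading))
    r[1] <- config$selection_loading
  r
}

#' Generate undisturbed test scores from a single common factor
#'
#' Constructs test `i` as `score_mean + score_sd * (r_i * z_g +
#' sqrt(1 - r_i^2) * e_i)` with `z_g` the population-standardised true g and
#' `e_i` i.i.d. standard normal, so each column has population mean
#' `score_mean`, SD `score_sd`, and population correlation exactly `r_i` with
#' g. Standardisation uses the population parameters, not the sample moments,
#' so per-sample correlations are left undistorted.
#'
#' @param true_g Vector of true g scores.
#' @param loadings Vector of population correlations `r_i`, all `|r_i| < 1`
#'   (`r_i = 1` is accepted as the degenerate noiseless limit).
#' @param config A [sim_config()] object (supplies the score metric).
#' @return `n x k` numeric matrix of undisturbed test scores.
#' @export
generate_true_scores <- function(true_g, loadings, config) {
  stopifnot(inherits(config, "slodr_config"))
  if (any(abs(loadings) > 1))
    stop("population correlations must lie in [-1, 1]", call. = FALSE)
  n <- length(true_g)
  k <- length(loadings)
  z_g <- (true_g - config$score_mean) / config$score_sd
  eps <- matrix(stats::rnorm(n * k), n, k)
  z <- z_g %*% t(loadings) + eps %*% diag(sqrt(1 - loadings^2), k, k)
  config$score_mean + config$score_sd * z
}

#' Draw the disturbance variable
#'
#' One beta draw per participant, in \[0, 1\], with shape parameters taken
#' from the config's shape map: Beta(9, 1) for negatively skewed, Beta(9, 9)
#' for approximately normal, Beta(1, 9) for positively skewed disturbance.
#' Lower values mean stronger disturbance.
#'
#' @param config A [sim_config()] with `disturbance_shape != "none"`.
#' @return Numeric vector of length `n_individuals` in \[0, 1\].
#' @export
draw_disturbance <- function(config) {
  stopifnot(inherits(config, "slodr_config"))
  if (config$disturbance_shape == "none")
    stop("no disturbance to draw when `disturbance_shape` is \"none\"", call. = FALSE)
  bp <- config$beta_params[[config$disturbance_shape]]
  stats::rbeta(config$n_individuals, bp[1], bp[2])
}

#' Multiply test scores by the disturbance variable
#'
#' Every score of participant `j` (selection variable included) is multiplied
#' by that participant's disturbance value `d_j` in \[0, 1\].
#'
#' @param true_scores `n x k` matrix of undisturbed scores.
#' @param disturbance Vector of length `n` with values in \[0, 1\].
#' @return `n x k` matrix of disturbed (observed) scores.
#' @export
apply_disturbance <- function(true_scores, disturbance) {
  if (nrow(true_scores) != length(disturbance))
    stop("row count of `true_scores` must match length of `disturbance`", call. = FALSE)
  if (any(disturbance < 0 | disturbance > 1))
    stop("disturbance values must lie in [0, 1]", call. = FALSE)
  true_scores * disturbance
}

#' Simulate one virtual population
#'
#' Runs the full generative chain under the config's seed: true g, population
#' loadings, undisturbed one-factor test scores, the disturbance draw (unless
#' the shape is `"none"`), and the disturbed observed scores.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `slodr_population`: a list with `true_g`,
#'   `loadings`, `true_scores`, `disturbance` (`NULL` when shape is
#'   `"none"`), `observed_scores`, and the generating `config`.
#' @examples
#' pop <- simulate_population(sim_config(n_individuals = 200, seed = 7,
#'                                       disturbance_shape = "negative"))
#' dim(pop$observed_scores)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "slodr_config"))
  set.seed(config$seed)
  true_g <- draw_true_g(config)
  loadings <- draw_loadings(config)
  true_scores <- generate_true_scores(true_g, loadings, config)
  colnames(true_scores) <- paste0("test", seq_len(config$n_tests))
  if (config$disturbance_shape == "none") {
    disturbance <- NULL
    observed <- true_scores
  } else {
    disturbance <- draw_disturbance(config)
    observed <- apply_disturbance(true_scores, disturbance)
  }
  structure(list(true_g = true_g,
                 loadings = loadings,
                 true_scores = true_scores,
                 disturbance = disturbance,
                 observed_scores = observed,
                 config = config),
            class = "slodr_population")
}

#' @export
print.slodr_population <- function(x, ...) {
  cat("<slodr_population>\n")
  cat(sprintf("  %d participants x %d tests, disturbance: %s\n",
              nrow(x$observed_scores), ncol(x$observed_scores),
              x$config$disturbance_shape))
  cat(sprintf("  true g: mean %.2f, sd %.2f\n", mean(x$true_g), stats::sd(x$true_g)))
  cat("  loadings:", paste(sprintf("%.2f", x$loadings), collapse = " "), "\n")
  invisible(x)
}

#' Export a population as a data frame
#'
#' One row per participant: true g, disturbance (1 when absent), and the
#' observed test scores. Convenient for CSV export and inspection.
#'
#' @param x A `slodr_population`.
#' @param ... Unused.
#' @return A data.frame with `2 + n_tests` columns.
#' @export
as.data.frame.slodr_population <- function(x, ...) {
  d <- if (is.null(x$disturbance)) rep(1, length(x$true_g)) else x$disturbance
  data.frame(true_g = x$true_g, disturbance = d, x$observed_scores)
}
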