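#' Regression-method factor scores
#'
#' Best linear predictor of the latent score(s) given the observed scores and
#' the fitted model: `ghat = Phi Lam' Sigma^-1 (x - mu)` per individual, with
#' `Phi = 1` for the one-factor model. Under the `var(g) = 1` identification
#' the scores are shrunken, so their variance never exceeds 1.
#'
#' @param fit A converged [fit_one_factor()] or [fit_linear_plus_quadratic()]
#'   fit.
#' @param observed_scores The score matrix the fit was obtained on (or new
#'   data with the same columns).
#' @return List of class `slodr_scores` with `g_hat` (length n) and, for a
#'   quadratic fit, `q_hat` (the estimated g-squared factor scores).
#' @export
predict_factor_scores <- function(fit, observed_scores) {
  stopifnot(inherits(fit, "slodr_cfa"))
  X <- as.matrix(observed_scores)
  if (ncol(X) != length(fit$loadings))
    stop("column count does not match the fitted model", call. = FALSE)
  ch <- tryCatch(chol(fit$implied_covariance), error = function(e) NULL)
  if (is.null(ch)) stop("implied covariance is singular", call. = FALSE)
  Sinv <- chol2inv(ch)
  Xc <- sweep(X, 2, fit$intercepts)
  if (inherits(fit, "slodr_quadcfa")) {
    sc <- Xc %*% Sinv %*% fit$loading_matrix %*% fit$latent_cov
    out <- list(g_hat = sc[, 1], q_hat = sc[, 2])
  } else {
    out <- list(g_hat = as.vector(Xc %*% Sinv %*% fit$loadings), q_hat = NULL)
  }
  structure(out, class = "slodr_scores")
}

#' Per-individual log residual variance
#'
#' For each individual, the model-predicted score on test i is
#' `mu_i + lambda_i * ghat`; the individual residual variance is the mean
#' over tests of the squared deviation of the observed from the predicted
#' score — the score variance the individual's estimated g does not account
#' for. The natural logarithm is returned, with the variance floored first so
#' degenerate noiseless data yield a finite (floor) value rather than -Inf.
#'
#' @param fit A [fit_one_factor()] fit.
#' @param observed_scores Matching score matrix.
#' @param g_hat Estimated factor scores for the same individuals.
#' @param floor Lower bound applied before taking logs (default 1e-12).
#' @return Numeric vector of length n: `log(max(residual variance, floor))`.
#' @export
individual_log_residual_variance <- function(fit, observed_scores, g_hat,
                                             floor = 1e-12) {
  stopifnot(inherits(fit, "slodr_cfa"))
  X <- as.matrix(observed_scores)
  if (nrow(X) != length(g_hat))
    stop("`g_hat` length must match the number of rows", call. = FALSE)
  pred <- outer(g_hat, fit$loadings) +
    matrix(fit$intercepts, nrow(X), ncol(X), byrow = TRUE)
  rv <- rowMeans((X - pred)^2)
  log(pmax(rv, floor))
}

#' Sample skewness with a significance test
#'
#' Sample skewness `g1 = m3 / m2^(3/2)` with the exact small-sample standard
#' error under normality, `SE = sqrt(6 n (n-1) / ((n-2) (n+1) (n+3)))`,
#' `z = g1 / SE`, and a two-sided normal p value.
#'
#' @param values Numeric vector, `n >= 8`, non-constant.
#' @return List with `skew`, `se`, `z`, `p`.
#' @examples
#' skewness_test(rbeta(5000, 9, 1))  # strongly negative
#' @export
skewness_test <- function(values) {
  n <- length(values)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  xc <- values - mean(values)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean(xc^3) / m2^1.5
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  z <- g1 / se
  list(skew = g1, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation with a two-sided t test
#'
#' @param a,b Numeric vectors of equal length `>= 3`, both non-constant.
#' @return List with `r`, `t`, `df`, `p`.
#' @export
correlation_with_p <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant input", call. = FALSE)
  r <- stats::cor(a, b)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, t = tt, df = n - 2L, p = 2 * stats::pt(-abs(tt), n - 2))
}
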