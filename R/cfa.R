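# Maximum-likelihood covariance-structure engine for the one-factor model
# and its quadratic extension. Identification: var(g) = 1, sign fixed so the
# loading sum is positive; means saturated (intercepts = sample means), so
# only the covariance structure is fitted.
#
# Both fits run on uniformly rescaled data (every variable divided by the
# same constant, the root mean variance) for optimizer conditioning. A
# uniform rescaling keeps the quadratic model's squared-loading constraint
# intact — x -> c x maps (lambda, theta, phi, psi) to (c lambda, c^2 theta,
# phi / c, psi / c^2) — so parameters are mapped back to the raw metric
# exactly. Column-wise standardisation would not preserve the constraint.

# ML (denominator n) covariance and its log determinant
ml_cov <- function(X) {
  n <- nrow(X)
  S <- stats::cov(X) * (n - 1) / n
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("sample covariance matrix is singular", call. = FALSE)
  list(S = S, logdet = 2 * sum(log(diag(ch))), mu = colMeans(X), n = n)
}

# Normal-theory discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - k and
# the weight matrix W = Sigma^-1 - Sigma^-1 S Sigma^-1 used by all gradients.
fml_parts <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Sinv <- chol2inv(ch)
  list(F = 2 * sum(log(diag(ch))) + sum(Sinv * S) - logdetS - ncol(S),
       W = Sinv - Sinv %*% S %*% Sinv,
       Sinv = Sinv)
}

fit_cov_structure <- function(S, logdetS, par0, sigma_fun, grad_fun, lower,
                              max_restarts = 3, stat_tol = 1e-8) {
  obj <- function(p) {
    parts <- fml_parts(sigma_fun(p), S, logdetS)
    if (is.null(parts) || !is.finite(parts$F)) return(1e10)
    parts$F
  }
  grad <- function(p) {
    parts <- fml_parts(sigma_fun(p), S, logdetS)
    if (is.null(parts)) return(rep(0, length(p)))
    grad_fun(p, parts$W)
  }
  ctrl <- list(eval.max = 2000, iter.max = 1000, rel.tol = 1e-10)
  best <- NULL
  par <- par0
  converged <- FALSE
  for (try in seq_len(max_restarts)) {
    res <- stats::nlminb(par, obj, grad, lower = lower, control = ctrl)
    if (is.null(best) || res$objective < best$objective) best <- res
    if (is.finite(best$objective) && best$objective < 1e9) {
      # stationarity check: restarting from the returned point must not
      # improve the discrepancy beyond stat_tol (nlminb's own codes
      # misreport "false/singular convergence" on flat ridges); stat_tol is
      # calibrated by the caller to the chi-square resolution the fit needs
      res2 <- stats::nlminb(best$par, obj, grad, lower = lower, control = ctrl)
      if (res2$objective < best$objective) best <- res2
      if (abs(res$objective - res2$objective) < stat_tol) {
        converged <- TRUE
        break
      }
    }
    # jittered restart from the best point so far
    par <- best$par * exp(stats::rnorm(length(par), sd = 0.05))
    par <- pmax(par, lower + 1e-8)
  }
  best$converged <- converged && is.finite(best$objective) && best$objective < 1e9
  best
}

#' Fit a one-factor confirmatory factor model by maximum likelihood
#'
#' Minimises the normal-theory discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - k` over the loadings and
#' residual variances of `Sigma = lambda lambda' + diag(theta)`, with the
#' latent variance fixed at 1 and intercepts saturated at the sample means.
#' An analytic gradient is used; on non-convergence the optimiser restarts
#' from up to three jittered points and the final fit is flagged.
#'
#' @param observed_scores `n x k` numeric matrix, `k >= 3`, `n > k`.
#' @return Object of class `slodr_cfa`: loadings (sign convention: positive
#'   sum), residual variances, intercepts, implied covariance, log-likelihood,
#'   discrepancy value, free-parameter count (2k), sample size, and
#'   `converged` / `heywood` flags.
#' @examples
#' pop <- simulate_population(sim_config(n_individuals = 800, seed = 3))
#' fit <- fit_one_factor(pop$observed_scores)
#' round(fit$loadings / sqrt(diag(fit$implied_covariance)), 2)  # corr metric
#' @export
fit_one_factor <- function(observed_scores) {
  X <- as.matrix(observed_scores)
  k <- ncol(X)
  if (k < 3) stop("need at least 3 indicators", call. = FALSE)
  if (nrow(X) <= k) stop("need more rows than columns", call. = FALSE)
  if (any(apply(X, 2, stats::var) == 0))
    stop("zero-variance column", call. = FALSE)
  mc <- ml_cov(X)
  scl <- 1 / sqrt(mean(diag(mc$S)))   # uniform rescale for conditioning
  S <- mc$S * scl^2

  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-8))
  if (sum(lam0) < 0) lam0 <- -lam0
  th0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
  th_floor <- 1e-6 * mean(diag(S))

  logdetS <- mc$logdet + 2 * k * log(scl)
  sigma_fun <- function(p) tcrossprod(p[1:k]) + diag(p[(k + 1):(2 * k)], k, k)
  grad_fun <- function(p, W) c(2 * as.vector(W %*% p[1:k]), diag(W))
  # converged = a restart moves the discrepancy by < 1/4 chi-square unit
  res <- fit_cov_structure(S, logdetS, c(lam0, th0), sigma_fun, grad_fun,
                           lower = c(rep(-Inf, k), rep(th_floor, k)),
                           stat_tol = 0.25 / mc$n)
  lam <- unname(res$par[1:k]) / scl
  if (sum(lam) < 0) lam <- -lam
  th <- unname(res$par[(k + 1):(2 * k)]) / scl^2
  th_floor <- th_floor / scl^2
  Sigma <- tcrossprod(lam) + diag(th, k, k)
  structure(list(loadings = lam,
                 residual_variances = th,
                 intercepts = mc$mu,
                 implied_covariance = Sigma,
                 discrepancy = res$objective,
                 loglik = -mc$n / 2 *
                   (k * log(2 * pi) + res$objective + mc$logdet + k),
                 n_free_params = 2L * k,
                 n = mc$n,
                 converged = res$converged,
                 heywood = any(th <= th_floor * 1.01),
                 sample_cov = mc$S),
            class = "slodr_cfa")
}

#' @export
print.slodr_cfa <- function(x, ...) {
  k <- length(x$loadings)
  cat(sprintf("<slodr_cfa> one-factor ML fit, %d indicators, n = %d\n", k, x$n))
  cat(sprintf("  discrepancy %.6g, loglik %.2f, converged: %s%s\n",
              x$discrepancy, x$loglik, x$converged,
              if (isTRUE(x$heywood)) " (Heywood)" else ""))
  cat("  loadings (corr metric):",
      paste(sprintf("%.2f", x$loadings / sqrt(diag(x$implied_covariance))),
            collapse = " "), "\n")
  invisible(x)
}

#' Fit the linear-plus-quadratic latent factor model
#'
#' Extends the one-factor model with a second latent factor representing the
#' square of g: `Sigma = Lam Phi Lam' + diag(theta)` with loading matrix
#' columns `(lambda_i)` and `(lambda_i^2)` — the quadratic loadings are a
#' hard elementwise-square constraint, not free parameters — and latent
#' covariance `Phi = [[1, phi], [phi, psi]]`, `var(g)` fixed at 1,
#' `phi = cov(g, g^2)` and `psi = var(g^2)` free. As in standard SEM
#' practice, `phi` and `psi` are unbounded during estimation (the implied
#' covariance just has to stay positive definite), so the naive two-degree
#' likelihood-ratio test against the one-factor model keeps its nominal
#' behaviour; a solution whose latent covariance matrix is not positive
#' semi-definite is flagged inadmissible rather than prevented. Two extra
#' free parameters relative to [fit_one_factor()].
#'
#' @param observed_scores `n x k` numeric matrix, `k >= 4`, `n > k`.
#' @param start Optional `slodr_cfa` one-factor fit on the same data used
#'   for starting values (computed internally when omitted).
#' @return Object of class `slodr_quadcfa`: all `slodr_cfa` fields plus
#'   `quad_variance` (psi), `quad_covariance` (phi), `latent_cov` (Phi), the
#'   `k x 2` loading matrix, and an `admissible` flag (`Phi` positive
#'   semi-definite).
#' @export
fit_linear_plus_quadratic <- function(observed_scores, start = NULL) {
  X <- as.matrix(observed_scores)
  k <- ncol(X)
  if (k < 4) stop("need at least 4 indicators for the quadratic model", call. = FALSE)
  if (nrow(X) <= k) stop("need more rows than columns", call. = FALSE)
  if (is.null(start)) start <- fit_one_factor(X)
  stopifnot(inherits(start, "slodr_cfa"))
  mc <- ml_cov(X)
  scl <- 1 / sqrt(mean(diag(mc$S)))
  S <- mc$S * scl^2
  logdetS <- mc$logdet + 2 * k * log(scl)
  th_floor <- 1e-6
  # par = (lambda, theta, phi, psi)
  sigma_fun <- function(p) {
    lam <- p[1:k]
    Lam <- cbind(lam, lam^2)
    Phi <- matrix(c(1, p[2 * k + 1], p[2 * k + 1], p[2 * k + 2]), 2, 2)
    Lam %*% Phi %*% t(Lam) + diag(p[(k + 1):(2 * k)], k, k)
  }
  grad_fun <- function(p, W) {
    lam <- p[1:k]
    Lam <- cbind(lam, lam^2)
    Phi <- matrix(c(1, p[2 * k + 1], p[2 * k + 1], p[2 * k + 2]), 2, 2)
    G <- W %*% Lam %*% Phi    # k x 2
    A <- crossprod(Lam, W %*% Lam)  # 2 x 2, = Lam' W Lam
    g_lam <- 2 * (G[, 1] + 2 * lam * G[, 2])
    c(g_lam, diag(W), 2 * A[1, 2], A[2, 2])
  }
  lam1 <- start$loadings * scl
  th1 <- pmax(start$residual_variances * scl^2, th_floor * 2)
  # psi starts away from 0, where the quadratic factor is absent
  par0 <- c(lam1, th1, 0, 0.5)
  res <- fit_cov_structure(S, logdetS, par0, sigma_fun, grad_fun,
                           lower = c(rep(-Inf, k), rep(th_floor, k), -Inf, -Inf),
                           stat_tol = 0.25 / mc$n)
  lam <- unname(res$par[1:k]) / scl
  flip <- sum(lam) < 0
  if (flip) lam <- -lam
  th <- unname(res$par[(k + 1):(2 * k)]) / scl^2
  a <- unname(res$par[2 * k + 1]) * scl
  psi <- unname(res$par[2 * k + 2]) * scl^2
  # flipping g negates cov(g, g^2) and leaves psi and lambda^2 loadings alone
  if (flip) a <- -a
  Lam <- cbind(linear = lam, quadratic = lam^2)
  Phi <- matrix(c(1, a, a, psi), 2, 2,
                dimnames = list(c("g", "g2"), c("g", "g2")))
  structure(list(loadings = lam,
                 loading_matrix = Lam,
                 residual_variances = th,
                 intercepts = mc$mu,
                 quad_covariance = a,
                 quad_variance = psi,
                 latent_cov = Phi,
                 implied_covariance = Lam %*% Phi %*% t(Lam) + diag(th, k, k),
                 discrepancy = res$objective,
                 loglik = -mc$n / 2 *
                   (k * log(2 * pi) + res$objective + mc$logdet + k),
                 n_free_params = 2L * k + 2L,
                 n = mc$n,
                 converged = res$converged,
                 heywood = any(th <= th_floor / scl^2 * 1.01),
                 admissible = psi >= 0 && psi - a^2 >= -1e-10,
                 sample_cov = mc$S),
            class = c("slodr_quadcfa", "slodr_cfa"))
}

#' @export
print.slodr_quadcfa <- function(x, ...) {
  cat(sprintf("<slodr_quadcfa> linear + quadratic latent fit, %d indicators, n = %d\n",
              length(x$loadings), x$n))
  cat(sprintf("  discrepancy %.6g, loglik %.2f, converged: %s%s\n",
              x$discrepancy, x$loglik, x$converged,
              if (!isTRUE(x$admissible)) " (inadmissible latent covariance)" else ""))
  cat(sprintf("  cov(g, g^2) = %.3f, var(g^2) = %.3f\n",
              x$quad_covariance, x$quad_variance))
  invisible(x)
}

#' Likelihood-ratio test of nested covariance-structure fits
#'
#' Chi-square difference test: `delta_chi2 = 2 (loglik_full -
#' loglik_restricted) = n (F_restricted - F_full)`, with degrees of freedom
#' the difference in free parameters (2 for the quadratic extension of the
#' one-factor model). Small negative differences within optimizer tolerance
#' are clamped to zero; larger ones raise an error since they signal a failed
#' optimisation of the full model.
#'
#' @param fit_restricted,fit_full Nested fits on the same data.
#' @return List with `delta_chi2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "slodr_cfa"), inherits(fit_full, "slodr_cfa"))
  if (fit_restricted$n != fit_full$n)
    stop("fits are not on the same data (different n)", call. = FALSE)
  df <- fit_full$n_free_params - fit_restricted$n_free_params
  if (df <= 0)
    stop("`fit_full` must have more free parameters than `fit_restricted`", call. = FALSE)
  delta <- 2 * (fit_full$loglik - fit_restricted$loglik)
  if (delta < -1e-4 * fit_full$n)
    stop("restricted model fits better than the full model; optimizer failure",
         call. = FALSE)
  delta <- max(delta, 0)
  list(delta_chi2 = delta, df = df,
       p = stats::pchisq(delta, df, lower.tail = FALSE))
}
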