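#' Rescale a variable to the conventional IQ metric
#'
#' Affine transform to sample mean exactly 100 and sample SD exactly 15.
#' Used on the (possibly disturbed) selection variable before forming
#' ability subgroups.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Rescaled numeric vector.
#' @export
rescale_to_iq_metric <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot rescale a constant (zero-variance) variable", call. = FALSE)
  100 + 15 * (values - mean(values)) / s
}

#' Form overlapping ability subgroups on the selection variable
#'
#' Ten windows of width 20 points on the rescaled selection variable, with
#' centers equally spaced between its 5th and 95th percentiles; each subgroup
#' collects the participants whose selection value falls in
#' `[center - 10, center + 10]`. Adjacent windows overlap, so participants
#' can belong to more than one subgroup, and each subgroup's internal range
#' never exceeds 20 points.
#'
#' @param sv_rescaled Selection variable already on the IQ metric.
#' @param n_groups Number of windows (default 10).
#' @param width Window width in selection-variable points (default 20).
#' @return An object of class `slodr_subgroups`: list with `members` (list of
#'   index vectors), `centers`, `window_bounds` (2-column matrix), and per
#'   group the mean selection value and size.
#' @export
form_subgroups <- function(sv_rescaled, n_groups = 10, width = 20) {
  if (length(sv_rescaled) < 100)
    stop("need at least 100 participants to form ability subgroups", call. = FALSE)
  qs <- stats::quantile(sv_rescaled, c(0.05, 0.95), names = FALSE)
  centers <- seq(qs[1], qs[2], length.out = n_groups)
  half <- width / 2
  members <- lapply(centers, function(cc)
    which(sv_rescaled >= cc - half & sv_rescaled <= cc + half))
  sizes <- lengths(members)
  if (any(sizes == 0L))
    stop("empty subgroup window; the selection variable distribution is ",
         "degenerate for this windowing", call. = FALSE)
  structure(list(members = members,
                 centers = centers,
                 window_bounds = cbind(low = centers - half, high = centers + half),
                 mean_sv = vapply(members, function(ix) mean(sv_rescaled[ix]), 0),
                 sizes = sizes),
            class = "slodr_subgroups")
}

#' @export
print.slodr_subgroups <- function(x, ...) {
  cat(sprintf("<slodr_subgroups> %d windows\n", length(x$members)))
  print(data.frame(center = round(x$centers, 1),
                   mean_sv = round(x$mean_sv, 1),
                   size = x$sizes))
  invisible(x)
}

#' Variance explained by the first unrotated principal component
#'
#' The g saturation index of the traditional paradigm: the largest eigenvalue
#' of the column correlation matrix divided by the number of columns, i.e.
#' the fraction of (standardised) test-score variance the first unrotated
#' principal component accounts for.
#'
#' @param score_matrix Numeric matrix, more rows than columns, at least two
#'   columns, no zero-variance column.
#' @return A single fraction in `[1/k, 1]`.
#' @export
first_pc_explained_variance <- function(score_matrix) {
  score_matrix <- as.matrix(score_matrix)
  k <- ncol(score_matrix)
  if (k < 2) stop("need at least 2 columns", call. = FALSE)
  if (nrow(score_matrix) <= k)
    stop("need more rows than columns for a stable correlation matrix", call. = FALSE)
  v <- apply(score_matrix, 2, stats::var)
  if (any(v == 0)) stop("zero-variance column", call. = FALSE)
  R <- stats::cor(score_matrix)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev[1] / k
}

#' One replicate of the traditional SLODR paradigm
#'
#' Simulates a population whose first test is the selection variable
#' (`selection_loading` must be set in the config), rescales the observed
#' selection variable to M = 100 / SD = 15, forms ten overlapping subgroups
#' within 20 points on it, and computes the first-PC explained variance of
#' the remaining tests inside each subgroup. A negative association between
#' the subgroup mean and the explained variance is the classical SLODR
#' signature; the Spearman rank correlation over the ten subgroups is
#' returned as a scalar trend summary.
#'
#' @param config A [sim_config()] with `selection_loading` set.
#' @return An object of class `slodr_traditional`: list with `subgroups` (a
#'   data.frame: subgroup, mean_sv, explained_variance, group_size),
#'   `trend_spearman`, and condition metadata.
#' @export
traditional_replicate <- function(config) {
  stopifnot(inherits(config, "slodr_config"))
  if (is.null(config$selection_loading))
    stop("`selection_loading` must be set for the traditional paradigm", call. = FALSE)
  pop <- simulate_population(config)
  sv <- rescale_to_iq_metric(pop$observed_scores[, 1])
  grp <- form_subgroups(sv)
  tests <- pop$observed_scores[, -1, drop = FALSE]
  ev <- vapply(grp$members,
               function(ix) first_pc_explained_variance(tests[ix, , drop = FALSE]),
               0)
  res <- data.frame(subgroup = seq_along(ev),
                    mean_sv = grp$mean_sv,
                    explained_variance = ev,
                    group_size = grp$sizes)
  structure(list(subgroups = res,
                 trend_spearman = stats::cor(res$mean_sv, res$explained_variance,
                                             method = "spearman"),
                 selection_loading = config$selection_loading,
                 disturbance_shape = config$disturbance_shape,
                 seed = config$seed),
            class = "slodr_traditional")
}

#' @export
print.slodr_traditional <- function(x, ...) {
  cat(sprintf("<slodr_traditional> selection loading %g, disturbance %s\n",
              x$selection_loading, x$disturbance_shape))
  print(x$subgroups, row.names = FALSE, digits = 3)
  cat(sprintf("Spearman trend (mean sv vs explained variance): %.3f\n",
              x$trend_spearman))
  invisible(x)
}
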