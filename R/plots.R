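# Optional ggplot2 figures. ggplot2 is a suggested dependency; the plotting
# functions are thin views over the tidy result tables.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting needs the ggplot2 package", call. = FALSE)
}

#' Plot explained variance against subgroup mean ability
#'
#' One panel per selection loading, one colour per disturbance condition,
#' one line per replicate: the classical picture of g saturation declining
#' with subgroup ability when scores are disturbed.
#'
#' @param x A `slodr_saturation` object from [run_traditional_experiment()].
#' @return A ggplot object.
#' @export
plot_explained_variance <- function(x) {
  stopifnot(inherits(x, "slodr_saturation"))
  need_ggplot()
  df <- x$subgroups
  df$panel <- sprintf("selection loading %.1f", df$selection_loading)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_sv,
                                   y = .data$explained_variance,
                                   group = interaction(.data$condition,
                                                       .data$replicate),
                                   colour = .data$condition)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "subgroup mean of the selection variable",
                  y = "variance explained by the first principal component",
                  colour = "disturbance") +
    ggplot2::theme_minimal()
}

#' Plot the single-run illustration
#'
#' Histogram of estimated g and the scatter of one observed test against
#' estimated g with linear and quadratic OLS fits overlaid.
#'
#' @param x A `slodr_illustration` object from [illustrate_single_run()].
#' @param which `"scatter"` (default) or `"histogram"`.
#' @return A ggplot object.
#' @export
plot_illustration <- function(x, which = c("scatter", "histogram")) {
  stopifnot(inherits(x, "slodr_illustration"))
  which <- match.arg(which)
  need_ggplot()
  if (which == "histogram") {
    df <- data.frame(g_hat = x$g_hat)
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$g_hat)) +
             ggplot2::geom_histogram(bins = 60, fill = "grey40") +
             ggplot2::labs(x = "estimated g",
                           y = "count",
                           title = sprintf("skew = %.3f (p = %.2g)",
                                           x$g_hat_skew$skew, x$g_hat_skew$p)) +
             ggplot2::theme_minimal())
  }
  df <- data.frame(g_hat = x$g_hat, score = x$test_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g_hat, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2), se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "estimated g",
                  y = sprintf("observed score, test %d", x$test_index)) +
    ggplot2::theme_minimal()
}
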