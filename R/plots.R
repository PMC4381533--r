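#' Kaplan-Meier plot
#'
#' Step curves of the product-limit survival estimate per group.
#'
#' @param object a `km_fit` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  curves <- dplyr::bind_rows(
    tibble::tibble(group = unique(object$curves$group), time = 0,
                   survival = 1),
    object$curves[, c("group", "time", "survival")])
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' SAM plot: observed d against expected null quantile
#'
#' The classic SAM quantile-quantile display; genes below the local-FDR gate
#' are highlighted.
#'
#' @param object a `sam_result`.
#' @param fdr_max highlighting threshold on the local FDR.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sam_result <- function(object, fdr_max = 0.05, ...) {
  t <- object$table
  df <- tibble::tibble(expected = qnorm(stats::ppoints(nrow(t))),
                       d = sort(t$d),
                       significant = t$fdr_local[order(t$d)] < fdr_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$d,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "Expected quantile", y = "Observed d",
                  colour = paste("local FDR <", fdr_max)) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for the matched random-list test
#'
#' Histogram of the log-rank chi-squares of the expression-matched random
#' gene lists, with the observed signature statistic marked.
#'
#' @param object a `matched_null`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.matched_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$stats),
                  ggplot2::aes(.data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "Log-rank chi-square (random lists)", y = "Count",
                  subtitle = sprintf("empirical P = %.4g",
                                     object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Boxplot of activation scores by subtype
#'
#' @param scores an `activation_scores` or named numeric vector.
#' @param subtypes subtype label per sample.
#' @return a ggplot.
#' @export
plot_scores_by_subtype <- function(scores, subtypes) {
  s <- if (inherits(scores, "activation_scores")) scores$scores else scores
  df <- tibble::tibble(subtype = as.character(subtypes), score = unname(s))
  ggplot2::ggplot(df, ggplot2::aes(.data$subtype, .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Activation score") +
    ggplot2::theme_minimal()
}
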