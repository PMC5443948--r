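ellipse_path <- function(cx, cy, rx, ry, n = 90) {
  th <- seq(0, 2 * pi, length.out = n)
  tibble(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

#' Discriminant-space scatterplot with one-SD ellipses
#'
#' The classic phenotypic-partitioning figure: each egg plotted on the
#' first two discriminant functions, with an ellipse per group whose
#' half-width and half-height are one standard deviation of DF1 and DF2.
#'
#' @param object An `egg_lda`.
#' @param data The data frame to project (defaults must be supplied).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.egg_lda <- function(object, data, ...) {
  ds <- df_scores(object, data)
  ell <- ds$ellipses %>%
    group_by(.data$group) %>%
    dplyr::reframe(ellipse_path(.data$centroid_df1, .data$centroid_df2,
                                .data$sd_df1, .data$sd_df2))
  ggplot2::ggplot(ds$scores, ggplot2::aes(x = .data$df1, y = .data$df2,
                                          colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$group)) +
    ggplot2::labs(x = "Discriminant function 1",
                  y = "Discriminant function 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pairwise-accuracy comparison plot
#'
#' Observed two-group accuracies for all species pairs, split by
#' parasitism status — the figure form of the pairwise partitioning
#' contrast.
#'
#' @param pairwise Long pairwise tibble with a `group` column (as
#'   produced by [run_pipeline()]).
#' @return A ggplot.
#' @export
plot_pairwise_accuracy <- function(pairwise) {
  ggplot2::ggplot(pairwise, ggplot2::aes(x = .data$group,
                                         y = .data$observed_pct)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Pairwise classification accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Mimicry-differential plot
#'
#' Own-host versus other-host accuracies per host-race; races below the
#' sample-size filter are shown hollow.
#'
#' @param object An `egg_mimicry`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.egg_mimicry <- function(object, ...) {
  mat <- filter(object$matrix, is.finite(.data$accuracy_pct))
  mat <- left_join(mat, object$races[c("race", "included")], by = "race")
  ggplot2::ggplot(mat, ggplot2::aes(x = .data$race, y = .data$accuracy_pct,
                                    colour = .data$comparison,
                                    shape = .data$included)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_jitter(width = 0.1)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "Race vs host accuracy (%)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
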