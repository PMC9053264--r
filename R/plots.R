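# ggplot2 views of the main result types.

#' Scatter plot of a 2-D projection
#'
#' @param coords A [project_2d()] tibble; if it has a `labels` column the
#'   points are coloured by it.
#' @return A ggplot.
#' @export
plot_projection <- function(coords) {
  p <- ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y))
  if ("labels" %in% names(coords)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$labels),
                                 size = 1, alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 1, alpha = 0.8)
  }
  p + ggplot2::labs(x = "dim 1", y = "dim 2") + ggplot2::theme_minimal()
}

#' Learning-curve plot
#'
#' @param curve A [learning_curve()] tibble (optionally several, row-bound
#'   with an `arm` column to compare sampling strategies).
#' @return A ggplot of mean validation micro-F1 against labeling budget,
#'   with standard-error ribbons.
#' @export
plot_learning_curve <- function(curve) {
  aes_args <- if ("arm" %in% names(curve)) {
    ggplot2::aes(.data$n_train, .data$mean_micro_f1, colour = .data$arm,
                 fill = .data$arm)
  } else {
    ggplot2::aes(.data$n_train, .data$mean_micro_f1)
  }
  ggplot2::ggplot(curve, aes_args) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_micro_f1 - .data$sem,
      ymax = .data$mean_micro_f1 + .data$sem), alpha = 0.2,
      colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "annotated synopses", y = "validation micro-F1") +
    ggplot2::theme_minimal()
}

#' Heatmap of top influential words per label
#'
#' @param table An [influence_table()].
#' @param k Words per label to keep (by normalized influence).
#' @return A ggplot tile heatmap (words x labels).
#' @export
plot_influence <- function(table, k = 5L) {
  top <- table |>
    group_by(.data$label) |>
    arrange(desc(.data$norm), .data$word, .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup()
  sub <- table[table$word %in% unique(top$word), ]
  ggplot2::ggplot(sub, ggplot2::aes(.data$label, .data$word,
                                    fill = .data$norm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "influence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-label F1 bar chart of an evaluation report
#'
#' @param report An [eval_metrics()] tibble.
#' @return A ggplot with per-label F1 bars and the micro-F1 as a reference
#'   line.
#' @export
plot_eval_report <- function(report) {
  per <- report[report$level == "label", ]
  micro <- report$f1[report$level == "micro"]
  ggplot2::ggplot(per, ggplot2::aes(stats::reorder(.data$label, .data$f1),
                                    .data$f1)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = micro, linetype = 2,
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "F1",
                  subtitle = sprintf("micro-F1 = %.3f", micro)) +
    ggplot2::theme_minimal()
}
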