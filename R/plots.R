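# ggplot2 views of the result objects.

#' Plot a cross-validation confusion matrix
#'
#' Row-percent confusion heatmap with cell annotations, matching how
#' condition/task accuracy is usually reported.
#'
#' @param object A `sway_cv` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sway_cv <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion, rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted",
                        values_to = "percent")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(
      title = sprintf("LOSO %s classification: %.1f%% accuracy",
                      object$target, object$accuracy),
      x = "predicted", y = "true", fill = "% of row")
}

#' Plot device agreement per task and joint
#'
#' @param object A `sway_benchmark` report.
#' @param ... Unused.
#' @return A ggplot object: mean Pearson r with one-SD error bars.
#' @export
autoplot.sway_benchmark <- function(object, ...) {
  df <- dplyr::mutate(object,
                      pair = paste0(.data$joint, " (", toupper(.data$axis), ")"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$task), .data$mean_r,
                                   color = .data$pair, group = .data$pair)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r),
      width = 0.2, position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(x = "task", y = "Pearson r (mean ± sd across subjects)",
                  color = "centroid (axis)") +
    ggplot2::ylim(NA, 1)
}

#' Plot a 2-D embedding coloured by task
#'
#' @param object A `sway_embedding` from [embed_2d()].
#' @param colour Metadata column to colour by (default `"task"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sway_embedding <- function(object, colour = "task", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2,
                                       color = factor(.data[[colour]]),
                                       shape = factor(.data$condition))) +
    ggplot2::geom_point() +
    ggplot2::labs(color = colour, shape = "condition",
                  x = "embedding 1", y = "embedding 2")
}

#' Plot a learning curve
#'
#' @param object A `sway_learning_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object: mean accuracy with a one-SD ribbon.
#' @export
autoplot.sway_learning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$train_size,
                                       .data$mean_accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training subjects", y = "condition accuracy (%)")
}
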