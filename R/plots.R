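#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the per-slice score
#' profile of a `stack_score`, and the ROC curve of a `roc_result` with its
#' Youden-optimal operating point marked. `plot_score_vs_mass()` shows a
#' score table against the true calcium masses with a least-squares line and
#' the Pearson R^2 per method.
#'
#' @param object the result object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name calscore-plots
NULL

#' @rdname calscore-plots
#' @export
autoplot.stack_score <- function(object, ...) {
  ggplot2::ggplot(object$per_slice,
                  ggplot2::aes(x = .data$slice_index, y = .data$score)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "slice index", y = "slice score (area x PV_max)",
      title = sprintf("%s %s-axis stack: total %.4g", object$modality,
                      object$axis_label, object$total_score)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname calscore-plots
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("point", x = 1 - object$spec_at_cutoff,
                      y = object$sens_at_cutoff, colour = "red", size = 2.5) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC: AUC = %.4f, cutoff = %.4g", object$auc,
                      object$optimal_cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname calscore-plots
#' @param score_table a long table with columns `mass_mg`, `method`, `value`,
#'   e.g. from [phantom_score_table()].
#' @export
plot_score_vs_mass <- function(score_table, ...) {
  labs_df <- score_table |>
    group_by(.data$method) |>
    summarise(
      r2 = pearson_r2(.data$mass_mg, .data$value)$r_squared,
      x = min(.data$mass_mg), y = max(.data$value)
    )
  ggplot2::ggplot(score_table, ggplot2::aes(x = .data$mass_mg, y = .data$value)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linewidth = 0.6) +
    ggplot2::geom_point() +
    ggplot2::geom_text(
      data = labs_df, hjust = 0, vjust = 1,
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = sprintf("R² = %.4f", .data$r2))
    ) +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = "calcium mass (mg)", y = "score") +
    ggplot2::theme_minimal()
}
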