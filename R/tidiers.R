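#' Tidy an evaluation: the confusion matrix in long form
#'
#' @param x A `wayfam_eval`.
#' @param ... Unused.
#' @return Tibble with `true`, `predicted`, `proportion`.
#' @export
tidy.wayfam_eval <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$confusion, responseName = "proportion")) |>
    dplyr::mutate(dplyr::across(c("true", "predicted"), as.character))
}

#' One-row evaluation summary
#'
#' @param x A `wayfam_eval`.
#' @param ... Unused.
#' @return Tibble with accuracy, final train/test log-loss and test size.
#' @export
glance.wayfam_eval <- function(x, ...) {
  final <- x$logloss_curve |>
    dplyr::group_by(.data$split) |>
    dplyr::slice_max(.data$round, n = 1) |>
    dplyr::ungroup()
  tibble::tibble(
    accuracy = x$accuracy,
    test_logloss = final$logloss[final$split == "test"][1],
    train_logloss = if ("train" %in% final$split) final$logloss[final$split == "train"][1] else NA_real_,
    n_test = x$n_test
  )
}

#' @rdname tidy.wayfam_eval
#' @export
tidy.wayfam_importance <- function(x, ...) x$ranks

#' @rdname tidy.wayfam_eval
#' @export
tidy.wayfam_experiment <- function(x, ...) x$runs

#' @rdname glance.wayfam_eval
#' @export
glance.wayfam_experiment <- function(x, ...) x$summary

#' Confusion-matrix heatmap
#'
#' @param object A `wayfam_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wayfam_eval <- function(object, ...) {
  tidy.wayfam_eval(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$predicted, y = .data$true,
                                 fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$proportion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(title = sprintf("Accuracy %.1f%%", 100 * object$accuracy),
                  x = "predicted condition", y = "true condition") +
    ggplot2::theme_minimal()
}

#' Train/test log-loss versus boosting rounds
#'
#' @param eval A `wayfam_eval`.
#' @return A ggplot.
#' @export
plot_logloss <- function(eval) {
  ggplot2::ggplot(eval$logloss_curve,
                  ggplot2::aes(x = .data$round, y = .data$logloss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of trees", y = "log-loss") +
    ggplot2::theme_minimal()
}

#' SHAP importance bar chart
#'
#' @param object A `wayfam_importance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wayfam_importance <- function(object, ...) {
  df <- object$ranks
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_shap,
                                   y = stats::reorder(.data$feature, .data$mean_abs_shap),
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP| (log-odds)", y = NULL, fill = "family") +
    ggplot2::theme_minimal()
}
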