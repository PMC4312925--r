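#' Plot methods
#'
#' `autoplot.scenario_report()` draws the per-correction group accuracy
#' bars (mean +/- SEM, chance line, significance stars) in the
#' red/blue/green convention: raw, mean-projected, RT-residualized.
#' `autoplot.group_result()` draws the permutation t distribution with the
#' observed t marked. `autoplot.subject_result()` draws the
#' cross-validation tuning trace across the C grid.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name mvpaproj-plots
NULL

correction_palette <- c(none = "#c0392b", mean_signal = "#2471a3",
                        response_time = "#1e8449")
correction_labels <- c(none = "raw", mean_signal = "mean-projected",
                       response_time = "RT-residualized")

#' @rdname mvpaproj-plots
#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- object$cells
  df$correction <- factor(df$correction, levels = names(correction_palette))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correction,
                                   y = .data$mean_accuracy,
                                   fill = .data$correction)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_accuracy - .data$sem,
                                        ymax = .data$mean_accuracy + .data$sem),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", ""),
                                    y = .data$mean_accuracy + .data$sem + 0.01),
                       size = 6) +
    ggplot2::scale_fill_manual(values = correction_palette, guide = "none") +
    ggplot2::scale_x_discrete(labels = correction_labels) +
    ggplot2::coord_cartesian(ylim = c(0.4, NA)) +
    ggplot2::labs(title = sprintf("Scenario: %s", object$scenario),
                  x = NULL, y = "group mean accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname mvpaproj-plots
#' @export
autoplot.group_result <- function(object, ...) {
  df <- tibble::tibble(t = object$perm_t_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$t_value, color = "#c0392b",
                        linewidth = 1) +
    ggplot2::labs(title = sprintf("Permutation null (%d draws), p = %.4f",
                                  object$n_permutations, object$p_value),
                  x = "group t under label permutation", y = "count") +
    ggplot2::theme_minimal()
}

#' @rdname mvpaproj-plots
#' @export
autoplot.subject_result <- function(object, ...) {
  cv <- object$fold_accuracies
  if (is.null(cv)) stopf("no tuning trace recorded for this result")
  agg <- dplyr::summarise(dplyr::group_by(cv, .data$C),
                          accuracy = mean(.data$accuracy, na.rm = TRUE))
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$C, y = .data$accuracy)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = agg, linewidth = 1, color = "#2471a3") +
    ggplot2::geom_vline(xintercept = object$chosen_c, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(title = sprintf("C tuning (chosen C = %g)", object$chosen_c),
                  x = "C (log scale)", y = "cross-validated accuracy") +
    ggplot2::theme_minimal()
}
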