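#' Plot a silhouette with an optional fitted sinusoid
#'
#' @param object A `silhouette` tibble.
#' @param fit Optional `sinusoid_fit` overlaid as a curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot silhouette
#' @export
autoplot.silhouette <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "position along long axis (mm)",
                  y = "inferior height (mm, down = inferior)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(min(object$x_mm), max(object$x_mm), length.out = 400)
    curve <- tibble(x_mm = xs,
                    y_mm = predict(fit, tibble(x_mm = xs)))
    p <- p + ggplot2::geom_line(data = curve, colour = "red")
  }
  p
}

#' Plot recovery-study results
#'
#' Fitted versus true amplitude per frequency level; perfect recovery lies
#' on the identity line.
#'
#' @param object A `recovery_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_table
#' @export
autoplot.recovery_table <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$true_A, y = .data$mean_A_hat,
                               colour = factor(.data$true_F))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "true amplitude (mm)", y = "mean fitted amplitude (mm)",
                  colour = "frequency\n(bump/mm)") +
    ggplot2::theme_minimal()
}

#' Box plots of dentation measures per group
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$group))) +
    ggplot2::geom_boxplot(ggplot2::aes(ymin = .data$whisker_lo,
                                       lower = .data$q1,
                                       middle = .data$median,
                                       upper = .data$q3,
                                       ymax = .data$whisker_hi),
                          stat = "identity") +
    ggplot2::facet_grid(measure ~ side, scales = "free_y") +
    ggplot2::labs(x = "group", y = "value") +
    ggplot2::theme_minimal()
}
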