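# ggplot2 graphics for the fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted-versus-observed plot of a fitted model
#'
#' @param object A `qsar_model`.
#' @param ... Unused.
#' @return A ggplot: fitted vs observed training activities with the
#'   identity line.
#' @export
autoplot.qsar_model <- function(object, ...) {
  df <- tibble::tibble(observed = object$observed, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "experimental log 1/c", y = "fitted log 1/c",
      title = sprintf("PLS fit: r² = %.2f, xr² = %.2f, RMSE = %.2f",
                      object$r2_train, object$xr2_loo, object$rmse_train)) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-experimental plot of a validation
#'
#' @param object A `qsar_validation`.
#' @param ... Unused.
#' @return A ggplot with outliers highlighted.
#' @export
autoplot.qsar_validation <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$experimental,
                                   y = .data$predicted,
                                   colour = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(
      x = "experimental log 1/c", y = "predicted log 1/c",
      title = sprintf("external validation: r² = %.2f, RMSE = %.2f",
                      object$metrics$r2, object$metrics$rmse)) +
    ggplot2::theme_minimal()
}

#' Potency-bin census plot of a pipeline run
#'
#' @param object A `qsar_run`.
#' @param ... Unused.
#' @return A ggplot bar chart of the low/medium/high census.
#' @export
autoplot.qsar_run <- function(object, ...) {
  df <- object$census
  df$bin <- factor(df$bin, levels = c("out_of_range", "low", "medium", "high"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "predicted potency bin", y = "molecules",
                  title = "predicted activity census") +
    ggplot2::theme_minimal()
}
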