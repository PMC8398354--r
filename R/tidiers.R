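# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted QSAR model
#'
#' @param x A `qsar_model`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept included):
#'   `term`, `estimate`.
#' @export
tidy.qsar_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$descriptors),
    estimate = c(x$intercept, unname(x$coefficients[x$descriptors]))
  )
}

#' One-row summary of a fitted QSAR model
#'
#' @param x A `qsar_model`.
#' @param ... Unused.
#' @return Tibble with `r2_train`, `r2_explained`, `xr2_loo`, `rmse_train`,
#'   `n_latent`, `n_descriptors`, `n_train`.
#' @export
glance.qsar_model <- function(x, ...) {
  tibble::tibble(
    r2_train = x$r2_train, r2_explained = x$r2_explained,
    xr2_loo = x$xr2_loo, rmse_train = x$rmse_train,
    n_latent = x$n_latent, n_descriptors = length(x$descriptors),
    n_train = x$n_train
  )
}

#' Tidy the published activity equation
#'
#' @param x A `published_model`.
#' @param ... Unused.
#' @return Tibble of terms and coefficients.
#' @export
tidy.published_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' Per-molecule residual table of a validation
#'
#' @param x A `qsar_validation`.
#' @param ... Unused.
#' @return Tibble `id, experimental, predicted, residual, outlier`.
#' @export
tidy.qsar_validation <- function(x, ...) x$residuals

#' One-row summary of a validation
#'
#' @param x A `qsar_validation`.
#' @param ... Unused.
#' @return Tibble `r2, r2_explained, rmse, n, n_outliers`.
#' @export
glance.qsar_validation <- function(x, ...) x$metrics

#' Descriptor-selection report
#'
#' @param x A `descriptor_selection`.
#' @param ... Unused.
#' @return Tibble `descriptor, r_activity, selected, reason`.
#' @export
tidy.descriptor_selection <- function(x, ...) x$report

#' One-row summary of a pipeline run
#'
#' @param x A `qsar_run`.
#' @param ... Unused.
#' @return Tibble with record counts and the headline metrics.
#' @export
glance.qsar_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$counts),
    tibble::tibble(
      r2_train = x$model$r2_train, xr2_loo = x$model$xr2_loo,
      rmse_train = x$model$rmse_train,
      r2_test = x$validation_test$metrics$r2,
      rmse_test = x$validation_test$metrics$rmse
    )
  )
}
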