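# The published five-descriptor activity equation, potency binning, and
# prediction helpers.

#' The published activity-prediction equation
#'
#' The fixed five-descriptor linear model for benzodiazepine GABA-A activity
#' (log 1/c, c the molar IC50 for displacing \[3H\]-diazepam):
#'
#' log 1/c = 9.45416 + 0.77505 h_log_pbo + 1.24990 kier_flex
#'           - 0.03382 q_vsa_hyd - 0.01507 slogp_vsa7 - 0.03849 vsa_pol
#'
#' @return An object of class `published_model` with elements `intercept`
#'   and `coefficients` (named numeric vector of length five).
#' @export
#' @examples
#' published_model()
published_model <- function() {
  structure(
    list(
      intercept = 9.45416,
      coefficients = c(h_log_pbo = 0.77505, kier_flex = 1.24990,
                       q_vsa_hyd = -0.03382, slogp_vsa7 = -0.01507,
                       vsa_pol = -0.03849)
    ),
    class = "published_model"
  )
}

#' @export
print.published_model <- function(x, ...) {
  cat("<published_model> log 1/c =", format(x$intercept), "+\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %+.5f * %s\n", x$coefficients[[nm]], nm))
  invisible(x)
}

#' Predict activity with the published equation
#'
#' Evaluates the fixed published equation on descriptor values.  Accepts a
#' data frame carrying the five descriptor columns (e.g. the output of
#' [featurize()]) and appends a `.pred` column, or a plain named numeric
#' vector / one-row list of the five descriptors.
#'
#' @param data Data frame with descriptor columns, or a named numeric vector.
#' @return The tibble with `.pred` appended, or a single numeric prediction.
#' @export
#' @examples
#' predict_published(c(h_log_pbo = 0, kier_flex = 0, q_vsa_hyd = 0,
#'                     slogp_vsa7 = 0, vsa_pol = 0))   # the intercept
predict_published <- function(data) {
  pm <- published_model()
  nms <- names(pm$coefficients)
  if (is.numeric(data) && !is.null(names(data))) {
    stopifnot(all(nms %in% names(data)))
    if (any(!is.finite(data[nms]))) stop("non-finite descriptor value", call. = FALSE)
    return(unname(pm$intercept + sum(pm$coefficients * data[nms])))
  }
  stopifnot(is.data.frame(data), all(nms %in% names(data)))
  X <- as.matrix(data[, nms, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite descriptor value", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(data),
                .pred = pm$intercept + as.vector(X %*% pm$coefficients))
}

#' Bin predicted activities into the published potency classes
#'
#' Low is `[5.80, 7.00)`, medium `[7.00, 8.00)`, high `[8.00, Inf)`; values
#' below 5.80 fall outside the span of the training activities and are
#' labelled `out_of_range` with a warning.
#'
#' @param value Numeric vector of (predicted) log 1/c values.
#' @return Factor with levels `out_of_range`, `low`, `medium`, `high`.
#' @export
#' @examples
#' bin_activity(c(8.61, 7.50, 6.99))
bin_activity <- function(value) {
  stopifnot(is.numeric(value))
  if (any(!is.finite(value))) stop("non-finite activity value", call. = FALSE)
  out <- cut(value, breaks = c(-Inf, 5.80, 7.00, 8.00, Inf),
             labels = c("out_of_range", "low", "medium", "high"),
             right = FALSE)
  if (any(out == "out_of_range"))
    warning(sum(out == "out_of_range"),
            " value(s) below 5.80, outside the modelled activity span")
  out
}

#' Flag prediction outliers
#'
#' A molecule is flagged when its prediction deviates from experiment by
#' strictly more than `threshold` log units.  By default the absolute
#' deviation is used so under-predicted compounds are caught as well;
#' `direction = "over"` restricts to over-predictions (predicted above
#' experimental), the stricter published reading.
#'
#' @param experimental,predicted Paired numeric vectors.
#' @param threshold Deviation threshold in log 1/c units (default 2.5).
#' @param direction `"both"` (absolute deviation, default) or `"over"`.
#' @return Logical vector: `TRUE` where flagged.
#' @export
#' @examples
#' flag_outliers(c(7, 7, 7), c(9.6, 7.1, 4.4))
flag_outliers <- function(experimental, predicted, threshold = 2.5,
                          direction = c("both", "over")) {
  direction <- match.arg(direction)
  stopifnot(length(experimental) == length(predicted),
            is.finite(experimental), is.finite(predicted), threshold >= 0)
  dev <- predicted - experimental
  if (direction == "over") dev > threshold else abs(dev) > threshold
}
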