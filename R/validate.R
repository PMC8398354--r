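# External validation and the similarity applicability domain.

#' Validate a QSAR model on a test set
#'
#' Predicts the test molecules, scores the predictions (r^2 as the squared
#' Pearson correlation of predicted vs experimental, plus the explained
#' variance, and RMSE) and flags outliers by the fixed deviation rule.
#'
#' @param model A `qsar_model`, or the `published_model()`.
#' @param test Data frame with descriptor and activity columns (featurised
#'   on the fly from `smiles` if necessary).
#' @param activity_col Name of the activity column.
#' @param outlier_threshold Deviation (log units) beyond which a molecule is
#'   flagged (default 2.5); see [flag_outliers()].
#' @param outlier_direction `"both"` or `"over"`, see [flag_outliers()].
#' @return Object of class `qsar_validation`: `metrics` (one-row tibble with
#'   `r2`, `r2_explained`, `rmse`, `n`, `n_outliers`) and `residuals`
#'   (per-molecule tibble with predictions, residuals and outlier flags).
#' @export
validate_qsar <- function(model, test, activity_col = "activity",
                          outlier_threshold = 2.5,
                          outlier_direction = c("both", "over")) {
  outlier_direction <- match.arg(outlier_direction)
  stopifnot(is.data.frame(test))
  if (nrow(test) == 0) stop("empty test set", call. = FALSE)
  stopifnot(activity_col %in% names(test))
  if (inherits(model, "published_model")) {
    if (!all(names(model$coefficients) %in% names(test)) && "smiles" %in% names(test))
      test <- featurize(test)
    preds <- predict_published(test)$.pred
  } else if (inherits(model, "qsar_model")) {
    preds <- predict(model, test)$.pred
  } else stop("model must be a qsar_model or published_model", call. = FALSE)
  y <- test[[activity_col]]
  stopifnot(all(is.finite(y)))
  out <- flag_outliers(y, preds, threshold = outlier_threshold,
                       direction = outlier_direction)
  res <- tibble::tibble(
    id = if ("id" %in% names(test)) test$id else as.character(seq_along(y)),
    experimental = y,
    predicted = preds,
    residual = preds - y,
    outlier = out
  )
  metrics <- tibble::tibble(
    r2 = if (length(y) >= 3 && stats::sd(preds) > 0) stats::cor(preds, y)^2 else NA_real_,
    r2_explained = 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean((y - preds)^2)),
    n = length(y),
    n_outliers = sum(out)
  )
  structure(list(metrics = metrics, residuals = res), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<qsar_validation> n = %d: r2 = %.3f, RMSE = %.3f, %d outlier(s)\n",
              m$n, m$r2, m$rmse, m$n_outliers))
  invisible(x)
}

#' Similarity applicability domain
#'
#' A prediction is considered inside the model's applicability domain when
#' the molecule's average Tanimoto similarity to the whole modelling dataset
#' reaches `cutoff`.  The average is always reported next to the verdict.
#'
#' @param data Data frame of query molecules (SMILES column required).
#' @param reference Data frame of the molecules used to train and validate
#'   the model.
#' @param cutoff Average-similarity threshold (default 0.5).
#' @param smiles_col SMILES column name in both frames.
#' @return `data` as a tibble with `avg_tc` and `in_domain` appended.
#' @export
applicability_domain <- function(data, reference, cutoff = 0.5,
                                 smiles_col = "smiles") {
  stopifnot(is.data.frame(data), is.data.frame(reference),
            smiles_col %in% names(data), smiles_col %in% names(reference))
  if (nrow(reference) == 0) stop("empty reference dataset", call. = FALSE)
  pool <- dataset_fingerprints(reference, smiles_col)
  avg <- vapply(data[[smiles_col]], function(s) {
    fp <- cached_molecule(s)$fp
    mean(vapply(pool, function(f) tanimoto(fp, f), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  dplyr::mutate(tibble::as_tibble(data),
                avg_tc = avg, in_domain = avg >= cutoff)
}
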