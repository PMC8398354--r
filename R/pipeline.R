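# End-to-end pipeline: configuration, orchestration and the run report.

#' Pipeline configuration
#'
#' Collects every numeric choice of the workflow in one validated object.
#' The defaults are the published study settings: curation at average
#' Tc 0.3, applicability domain at average Tc 0.5, descriptor-activity
#' correlation filter at 0.5, mutual collinearity limit 0.7, outlier rule
#' 2.5 log units, 80/20 training split, potency bin edges 5.80 / 7.00 /
#' 8.00.
#'
#' @param tc_curation Average-similarity curation cutoff.
#' @param tc_domain Applicability-domain cutoff.
#' @param activity_corr Minimum |r| of a descriptor to the activity.
#' @param collinearity Maximum mutual |r| between kept descriptors.
#' @param outlier Outlier deviation threshold (log units).
#' @param outlier_direction `"both"` or `"over"`, see [flag_outliers()].
#' @param bin_edges Lower edges of the low / medium / high potency bins.
#' @param train_fraction Training-set fraction of the split.
#' @param seed Integer seed used by every stochastic stage.
#' @param log_base Logarithm base of the pi-bond-order descriptor.
#' @param hyd_threshold |charge| cutoff of the hydrophobic VSA partition.
#' @param n_latent Latent-variable count (`NULL` = choose by LOO).
#' @return A `qsar_config` list.
#' @export
qsar_config <- function(tc_curation = 0.3, tc_domain = 0.5,
                        activity_corr = 0.5, collinearity = 0.7,
                        outlier = 2.5, outlier_direction = "both",
                        bin_edges = c(5.80, 7.00, 8.00),
                        train_fraction = 0.8, seed = 1L,
                        log_base = exp(1), hyd_threshold = 0.2,
                        n_latent = NULL) {
  stopifnot(tc_curation >= 0, tc_curation <= 1, tc_domain >= 0, tc_domain <= 1,
            activity_corr >= 0, activity_corr <= 1,
            collinearity >= 0, collinearity <= 1,
            outlier >= 0, length(bin_edges) == 3, !is.unsorted(bin_edges),
            train_fraction > 0, train_fraction < 1, log_base > 0,
            hyd_threshold >= 0)
  structure(list(
    tc_curation = tc_curation, tc_domain = tc_domain,
    activity_corr = activity_corr, collinearity = collinearity,
    outlier = outlier, outlier_direction = outlier_direction,
    bin_edges = bin_edges, train_fraction = train_fraction,
    seed = as.integer(seed), log_base = log_base,
    hyd_threshold = hyd_threshold, n_latent = n_latent
  ), class = "qsar_config")
}

#' @export
print.qsar_config <- function(x, ...) {
  cat("<qsar_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "auto" else paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

# census of predictions over the potency bins
bin_census <- function(pred) {
  bins <- suppressWarnings(bin_activity(pred))
  counts <- table(bins)
  tibble::tibble(
    bin = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / length(pred), 1),
    percent_int = as.integer(round(100 * as.integer(counts) / length(pred)))
  )
}

#' Run the full QSAR workflow
#'
#' Executes the end-to-end cascade on a molecule table with activities:
#' featurise, curate by average similarity, stratified train/test split,
#' descriptor selection, PLS fit with LOO cross-validation, internal and
#' external validation with outlier flagging, and finally prediction,
#' potency binning and applicability-domain assessment of a screening set
#' (by default the model's own input; optionally a separate table of
#' molecules without activities).
#'
#' @param data Data frame `id, smiles, activity`, e.g. from [bzd_library()]
#'   or [read_molecules()].  If `NULL`, a synthetic training library is
#'   generated with [bzd_library()]`(n, seed, sigma)`.
#' @param screen Optional data frame of molecules to predict and bin with
#'   the fitted model (default: the curated input itself).
#' @param config A [qsar_config()].
#' @param n,sigma Size and noise of the synthetic library when `data` is
#'   `NULL`.
#' @return Object of class `qsar_run`: the config, stage-by-stage record
#'   counts, the selection report, the fitted `qsar_model`, train and test
#'   `qsar_validation`s, the prediction table (with bins and domain
#'   verdicts), the bin census, and accumulated warnings.
#' @export
run_pipeline <- function(data = NULL, screen = NULL, config = qsar_config(),
                         n = 76, sigma = 0.3) {
  stopifnot(inherits(config, "qsar_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  if (is.null(data)) {
    data <- bzd_library(n, seed = config$seed, sigma = sigma)
    note("synthetic library generated: n = %d, seed = %d, sigma = %g",
         n, config$seed, sigma)
  }
  stopifnot(is.data.frame(data), all(c("smiles", "activity") %in% names(data)))
  counts <- list(input = nrow(data))
  feats <- featurize(data, log_base = config$log_base,
                     hyd_threshold = config$hyd_threshold)
  counts$featurised <- nrow(feats)
  if (nrow(feats) < nrow(data))
    note("%d record(s) failed to featurise", nrow(data) - nrow(feats))
  curated <- curate(feats, cutoff = config$tc_curation)
  counts$curated <- nrow(curated)
  removed <- attr(curated, "removed")
  if (nrow(removed))
    note("curation removed %d molecule(s): %s", nrow(removed),
         paste(removed$id, collapse = ", "))
  split <- split_dataset(curated, train_fraction = config$train_fraction,
                         seed = config$seed)
  train <- dplyr::filter(split, .data$set == "train")
  test <- dplyr::filter(split, .data$set == "test")
  counts$train <- nrow(train); counts$test <- nrow(test)
  selection <- select_descriptors(train, corr_cutoff = config$activity_corr,
                                  collinearity_cutoff = config$collinearity)
  model <- fit_qsar(train, selection$selected, n_latent = config$n_latent)
  val_train <- validate_qsar(model, train,
                             outlier_threshold = config$outlier,
                             outlier_direction = config$outlier_direction)
  val_test <- validate_qsar(model, test,
                            outlier_threshold = config$outlier,
                            outlier_direction = config$outlier_direction)
  # prediction / binning / applicability domain on the screening set
  if (is.null(screen)) screen <- curated
  if (!all(model$descriptors %in% names(screen)))
    screen <- featurize(screen, log_base = config$log_base,
                        hyd_threshold = config$hyd_threshold)
  preds <- predict(model, screen)
  preds <- applicability_domain(preds, reference = curated,
                                cutoff = config$tc_domain)
  preds <- dplyr::mutate(
    preds,
    .pred_2dp = round(.data$.pred, 2),
    bin = suppressWarnings(bin_activity(.data$.pred)))
  counts$predicted <- nrow(preds)
  census <- bin_census(preds$.pred)
  structure(list(
    config = config, counts = counts, selection = selection, model = model,
    validation_train = val_train, validation_test = val_test,
    predictions = preds, census = census, warnings = warnings_log
  ), class = "qsar_run")
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("<qsar_run>\n  records:",
      paste(sprintf("%s=%d", names(x$counts), unlist(x$counts)), collapse = ", "),
      "\n")
  cat(sprintf("  model: %d descriptors (%s), %d latent\n",
              length(x$model$descriptors),
              paste(x$model$descriptors, collapse = ", "), x$model$n_latent))
  cat(sprintf("  train: r2 = %.3f, xr2 = %.3f, RMSE = %.3f\n",
              x$model$r2_train, x$model$xr2_loo, x$model$rmse_train))
  m <- x$validation_test$metrics
  cat(sprintf("  test:  r2 = %.3f, RMSE = %.3f (n = %d, %d outlier(s))\n",
              m$r2, m$rmse, m$n, m$n_outliers))
  cat("  bin census:\n")
  for (i in seq_len(nrow(x$census)))
    cat(sprintf("    %-12s %3d (%.1f%%)\n", x$census$bin[i], x$census$n[i],
                x$census$percent[i]))
  if (length(x$warnings)) cat("  notes:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}
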