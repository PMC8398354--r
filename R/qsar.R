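# Dataset curation, stratified splitting, and descriptor selection — the
# model-building cascade upstream of the PLS fit.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# fingerprints for every row of a molecule table (cached per SMILES)
dataset_fingerprints <- function(data, smiles_col = "smiles") {
  lapply(data[[smiles_col]], function(s) cached_molecule(s)$fp)
}

#' Curate a dataset by average Tanimoto similarity
#'
#' Computes, for every molecule, the mean Tanimoto coefficient against all
#' other molecules of the dataset and removes molecules whose average falls
#' below `cutoff` — structural strays that would dilute a single-class QSAR
#' model.
#'
#' @param data Data frame with a SMILES column.
#' @param cutoff Average-similarity threshold (default 0.3).
#' @param smiles_col Name of the SMILES column.
#' @return Tibble of retained rows with an `avg_tc` column appended; the
#'   removed rows (with their averages) are attached as attribute
#'   `"removed"`.
#' @export
curate <- function(data, cutoff = 0.3, smiles_col = "smiles") {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  if (nrow(data) < 2) stop("curation needs at least two molecules", call. = FALSE)
  fps <- dataset_fingerprints(data, smiles_col)
  avg <- average_tc_matrixwise(fps)
  out <- dplyr::mutate(tibble::as_tibble(data), avg_tc = avg)
  keep <- avg >= cutoff
  if (!any(keep))
    stop("curation removed every molecule (max average Tc = ",
         format(max(avg), digits = 3), ")", call. = FALSE)
  removed <- out[!keep, , drop = FALSE]
  if (nrow(removed))
    message(nrow(removed), " molecule(s) removed at average Tc < ", cutoff)
  res <- out[keep, , drop = FALSE]
  attr(res, "removed") <- removed
  res
}

#' Stratified training/test split by activity and similarity
#'
#' Joint quantile stratification: molecules are grouped by activity quartile
#' crossed with a median split on average Tanimoto similarity to the rest of
#' the dataset, and each stratum contributes its share of the test set.  The
#' most and least active molecules are always kept in the training set so
#' the test activities lie inside the training range.  Strata too small to
#' sample from trigger a fallback to activity-only stratification.
#'
#' @param data Curated data frame with SMILES and activity columns.
#' @param train_fraction Fraction of molecules in the training set (default 0.8).
#' @param seed Integer seed making the draw reproducible.
#' @param activity_col,smiles_col Column names.
#' @return The input tibble with a `set` column (`"train"` / `"test"`).
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L,
                          activity_col = "activity", smiles_col = "smiles") {
  stopifnot(is.data.frame(data), activity_col %in% names(data),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(data)
  if (n < 10) stop("need at least 10 molecules to split", call. = FALSE)
  act <- data[[activity_col]]
  stopifnot(all(is.finite(act)))
  if ("avg_tc" %in% names(data)) {
    avg <- data$avg_tc
  } else {
    avg <- average_tc_matrixwise(dataset_fingerprints(data, smiles_col))
  }
  act_q <- dplyr::ntile(act, 4)
  sim_h <- dplyr::ntile(avg, 2)
  stratum <- paste(act_q, sim_h)
  if (min(table(stratum)) < 2) {
    warning("strata too small; falling back to activity-only stratification")
    stratum <- as.character(act_q)
  }
  n_test_target <- round(n * (1 - train_fraction))
  idx_test <- with_seed(seed, {
    picks <- integer(0)
    for (s in unique(stratum)) {
      members <- which(stratum == s)
      k <- round(length(members) * (1 - train_fraction))
      if (k > 0) picks <- c(picks, sample(members, k))
    }
    # nudge the total onto the target count
    while (length(picks) > n_test_target && length(picks) > 0)
      picks <- picks[-sample.int(length(picks), 1)]
    pool <- setdiff(seq_len(n), picks)
    while (length(picks) < n_test_target && length(pool) > 2)
      { add <- sample(pool, 1); picks <- c(picks, add); pool <- setdiff(pool, add) }
    picks
  })
  # pin the activity extremes to the training set
  idx_test <- setdiff(idx_test, c(which.min(act), which.max(act)))
  out <- dplyr::mutate(tibble::as_tibble(data),
                       set = ifelse(seq_len(n) %in% idx_test, "test", "train"))
  out
}

#' Two-stage descriptor selection
#'
#' Stage one keeps descriptors whose absolute Pearson correlation with the
#' activity is at least `corr_cutoff`; stage two walks the surviving mutual
#' correlation matrix and, for every pair above `collinearity_cutoff`, drops
#' the member with the weaker activity correlation, until no collinear pair
#' remains.
#'
#' @param data Data frame holding descriptor and activity columns.
#' @param descriptors Character vector of candidate descriptor columns
#'   (default the five model descriptors).
#' @param activity_col Name of the activity column.
#' @param corr_cutoff Minimum |r| to the activity (default 0.5).
#' @param collinearity_cutoff Maximum allowed mutual |r| (default 0.7).
#' @return Object of class `descriptor_selection`: list with `selected`
#'   (character vector), `report` (tibble of all candidates, correlations and
#'   fate) and `cor_matrix` (mutual correlations of the candidates).
#' @export
select_descriptors <- function(data, descriptors = descriptor_names(),
                               activity_col = "activity",
                               corr_cutoff = 0.5, collinearity_cutoff = 0.7) {
  stopifnot(is.data.frame(data), all(descriptors %in% names(data)),
            activity_col %in% names(data), length(descriptors) >= 2,
            nrow(data) >= 10)
  X <- as.matrix(data[, descriptors, drop = FALSE])
  y <- data[[activity_col]]
  sds <- apply(X, 2, stats::sd)
  r_act <- rep(0, length(descriptors))
  names(r_act) <- descriptors
  ok <- sds > 0
  r_act[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  keep <- abs(r_act) >= corr_cutoff & ok
  reason <- ifelse(!ok, "zero variance",
                   ifelse(keep, "", sprintf("|r| to activity %.3f < %.2f",
                                            abs(r_act), corr_cutoff)))
  survivors <- descriptors[keep]
  cm <- if (sum(ok) >= 2) stats::cor(X[, ok, drop = FALSE]) else NULL
  # greedy collinearity pruning
  while (length(survivors) >= 2) {
    sub <- stats::cor(X[, survivors, drop = FALSE])
    diag(sub) <- 0
    if (max(abs(sub)) <= collinearity_cutoff) break
    worst <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1, ]
    pair <- survivors[worst]
    drop <- pair[which.min(abs(r_act[pair]))]
    reason[descriptors == drop] <-
      sprintf("collinear with %s (|r| = %.3f)", setdiff(pair, drop),
              max(abs(sub)))
    survivors <- setdiff(survivors, drop)
  }
  if (length(survivors) == 0) {
    best <- descriptors[order(abs(r_act), decreasing = TRUE)][1:min(3, length(descriptors))]
    stop("no descriptor survives selection; best candidates: ",
         paste(sprintf("%s (r = %.3f)", best, r_act[best]), collapse = ", "),
         call. = FALSE)
  }
  report <- tibble::tibble(
    descriptor = descriptors,
    r_activity = unname(r_act),
    selected = descriptors %in% survivors,
    reason = reason
  )
  structure(list(selected = survivors, report = report, cor_matrix = cm),
            class = "descriptor_selection")
}

#' @export
print.descriptor_selection <- function(x, ...) {
  cat("<descriptor_selection>", length(x$selected), "of",
      nrow(x$report), "descriptors kept:",
      paste(x$selected, collapse = ", "), "\n")
  print(x$report)
  invisible(x)
}
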