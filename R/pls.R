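# Partial least squares (PLS1) regression with leave-one-out
# cross-validation — the regression engine of the model-building cascade.

# NIPALS PLS1 on centred (and optionally autoscaled) data.  Returns the
# regression coefficients on the original descriptor scale.
pls1_fit <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, ncomp >= 1, ncomp <= p)
  if (stats::sd(y) == 0) stop("constant response; nothing to fit", call. = FALSE)
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(xs == 0)) stop("zero-variance descriptor column", call. = FALSE)
  ym <- mean(y)
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }   # response fully explained
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  if (ncomp == 0) stop("response uncorrelated with every descriptor", call. = FALSE)
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(t(P) %*% W, q)           # coefficients, scaled space
  b <- as.vector(B) / xs                    # back to original units
  intercept <- ym - sum(b * xm)
  fitted <- as.vector(X %*% b) + intercept
  list(coefficients = stats::setNames(b, colnames(X)), intercept = intercept,
       n_latent = ncomp, fitted = fitted)
}

#' Leave-one-out cross-validated correlation (xr^2)
#'
#' Refits the PLS model without each sample in turn and scores the held-out
#' predictions: `xr2 = 1 - sum((y - yhat_(-i))^2) / sum((y - mean(y))^2)`.
#'
#' @param X Descriptor matrix (or data frame).
#' @param y Activity vector.
#' @param n_latent Number of latent variables.
#' @param scale Autoscale descriptors (default `TRUE`).
#' @return The cross-validated xr^2 (at most 1; can be negative).
#' @export
loo_xr2 <- function(X, y, n_latent, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  press <- 0
  for (i in seq_len(n)) {
    fit <- pls1_fit(X[-i, , drop = FALSE], y[-i], n_latent, scale = scale)
    pred <- sum(fit$coefficients * X[i, ]) + fit$intercept
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Fit a PLS QSAR model
#'
#' Fits a PLS1 regression of activity on the selected descriptors.  When
#' `n_latent` is not given, the latent-variable count maximising the
#' leave-one-out xr^2 is chosen (capped at the descriptor count).
#' Coefficients are reported on the original descriptor scale.
#'
#' @param data Data frame with descriptor and activity columns (typically
#'   the training rows of a featurised, curated, split dataset).
#' @param descriptors Character vector of descriptor columns to use.
#' @param activity_col Name of the activity column.
#' @param n_latent Number of latent variables, or `NULL` to select by LOO.
#' @param scale Autoscale descriptors before fitting (default `TRUE`).
#' @return Object of class `qsar_model`: coefficients, intercept, latent
#'   count, training metrics (`r2_train`, `xr2_loo`, `rmse_train`) and the
#'   fitted values.
#' @export
fit_qsar <- function(data, descriptors = descriptor_names(),
                     activity_col = "activity", n_latent = NULL, scale = TRUE) {
  stopifnot(is.data.frame(data), all(descriptors %in% names(data)),
            activity_col %in% names(data))
  X <- as.matrix(data[, descriptors, drop = FALSE])
  y <- data[[activity_col]]
  stopifnot(all(is.finite(X)), all(is.finite(y)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(descriptors[sds == 0], collapse = ", "))
    descriptors <- descriptors[sds > 0]
    X <- X[, descriptors, drop = FALSE]
  }
  if (nrow(X) < 10 * length(descriptors))
    message("note: fewer than ten molecules per descriptor (",
            nrow(X), " for ", length(descriptors), ")")
  p <- length(descriptors)
  if (is.null(n_latent)) {
    scores <- vapply(seq_len(p), function(a)
      loo_xr2(X, y, a, scale = scale), numeric(1))
    n_latent <- which.max(scores)
    xr2 <- scores[n_latent]
  } else {
    stopifnot(n_latent >= 1, n_latent <= p)
    xr2 <- loo_xr2(X, y, n_latent, scale = scale)
  }
  fit <- pls1_fit(X, y, n_latent, scale = scale)
  structure(list(
    descriptors = descriptors,
    coefficients = fit$coefficients,
    intercept = fit$intercept,
    n_latent = fit$n_latent,
    scale = scale,
    r2_train = stats::cor(fit$fitted, y)^2,
    r2_explained = 1 - sum((y - fit$fitted)^2) / sum((y - mean(y))^2),
    xr2_loo = xr2,
    rmse_train = sqrt(mean((y - fit$fitted)^2)),
    fitted = fit$fitted,
    observed = y,
    n_train = nrow(X),
    activity_col = activity_col
  ), class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> PLS, %d latent variable(s), %d descriptors, n = %d\n",
              x$n_latent, length(x$descriptors), x$n_train))
  cat(sprintf("  r2 = %.3f  xr2(LOO) = %.3f  RMSE = %.3f\n",
              x$r2_train, x$xr2_loo, x$rmse_train))
  cat("  log 1/c =", format(round(x$intercept, 5)))
  for (nm in x$descriptors)
    cat(sprintf(" %+g*%s", round(x$coefficients[[nm]], 5), nm))
  cat("\n")
  invisible(x)
}

#' Predict from a fitted QSAR model
#'
#' @param object A `qsar_model`.
#' @param newdata Data frame containing the model's descriptor columns
#'   (molecules are featurised first if a `smiles` column is present and the
#'   descriptors are not).
#' @param ... Unused.
#' @return `newdata` as a tibble with a `.pred` column appended.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!all(object$descriptors %in% names(newdata)) && "smiles" %in% names(newdata))
    newdata <- featurize(newdata)
  stopifnot(all(object$descriptors %in% names(newdata)))
  X <- as.matrix(newdata[, object$descriptors, drop = FALSE])
  dplyr::mutate(tibble::as_tibble(newdata),
                .pred = as.vector(X %*% object$coefficients) + object$intercept)
}
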