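#' Stack per-channel log-PSD into a feature matrix
#'
#' Builds the epochs x (frequencies * channels) matrix whose column block j
#' holds the kept frequency bins of channel j (channel-major order).  With
#' 40 bins and 4 channels this is the 160-column feature matrix of the
#' standard modeling scheme.
#'
#' @param psd a `psd_timeseries`.
#' @param channels channel labels, a subset of `psd$channel_names`.
#' @param rows optional epoch (row) selection.
#' @return numeric matrix with attributes `channels` and `freqs`.
#' @export
stack_features <- function(psd, channels, rows = NULL) {
  stopifnot(inherits(psd, "psd_timeseries"))
  idx <- match(channels, psd$channel_names)
  if (anyNA(idx)) {
    stop(sprintf("unknown channel(s): %s",
                 paste(channels[is.na(idx)], collapse = ", ")))
  }
  if (is.null(rows)) rows <- seq_along(psd$epoch_times)
  X <- do.call(cbind, lapply(idx, function(i) psd$logpower[rows, i, , drop = TRUE]))
  if (length(rows) == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- as.vector(outer(psd$freqs, channels,
                                 function(f, ch) paste0(ch, ".", f)))
  attr(X, "channels") <- channels
  attr(X, "freqs") <- psd$freqs
  X
}

#' Fit the retained eigenbasis of a feature matrix
#'
#' Principal component analysis of the column-centered features: the
#' eigenvectors of the sample covariance whose eigenvalues explain at
#' least `threshold` (default 1%) of the total variance are retained, in
#' descending eigenvalue order.  If no component reaches the threshold the
#' single largest is kept (degenerate-input guard).  Column means are
#' stored for test-time centering.
#'
#' @param X feature matrix (epochs x features), `n >= 2`.
#' @param threshold minimum explained-variance share (default 0.01).
#' @return An object of class `spectral_basis`: `V` (columns = retained
#'   eigenvectors), `lambda` (all eigenvalues, descending), `shares`,
#'   `means`, `threshold`.
#' @export
fit_basis <- function(X, threshold = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to fit a basis")
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means, "-")
  C <- crossprod(Xc) / (n - 1)
  total <- sum(diag(C))
  if (total <= 0) stop("zero-variance feature matrix")
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  shares <- lambda / total
  keep <- which(shares >= threshold)
  if (length(keep) == 0L) keep <- 1L
  V <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(V = V, lambda = lambda, shares = shares, means = means,
         threshold = threshold, channels = attr(X, "channels"),
         freqs = attr(X, "freqs")),
    class = "spectral_basis"
  )
}

#' Fit the linear regression of behavior on eigenbasis projections
#'
#' Ordinary least squares (with intercept) of the behavioral series on the
#' projections of the centered features onto the retained eigenvectors.
#' No temporal lag is included: each epoch's spectrum predicts the
#' behavior at that epoch.
#'
#' @param X feature matrix used for training (epochs x features).
#' @param basis a `spectral_basis` fit on training data.
#' @param y behavioral values aligned to the rows of `X`.
#' @param metric metric label stored in the model.
#' @return An object of class `spectral_model`: `basis`, `beta` (one
#'   coefficient per retained eigenvector), `intercept`, `channels`,
#'   `metric`.
#' @export
fit_model <- function(X, basis, y, metric = "behavior") {
  X <- as.matrix(X)
  m <- ncol(basis$V)
  if (nrow(X) < m + 2L) stop("fewer rows than coefficients")
  if (nrow(X) != length(y)) stop("X/y length mismatch")
  Z <- sweep(X, 2L, basis$means, "-") %*% basis$V
  fit <- lm.fit(cbind(1, Z), y)
  structure(
    list(basis = basis, beta = unname(fit$coefficients[-1L]),
         intercept = unname(fit$coefficients[1L]),
         channels = basis$channels, metric = metric),
    class = "spectral_model"
  )
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf(
    "<spectral_model> metric '%s', %d channel(s) [%s], %d component(s)\n",
    x$metric, length(x$channels), paste(x$channels, collapse = ", "),
    length(x$beta)
  ))
  invisible(x)
}

#' Estimate behavior from a PSD time series
#'
#' Applies a fitted model: stack the model's channels, center with the
#' training means, project onto the retained eigenvectors, and apply the
#' regression coefficients.  The output lives on the PSD epoch grid.
#'
#' @param model a `spectral_model`.
#' @param psd a `psd_timeseries` (smoothed like the training data) covering
#'   the model's channels.
#' @param rows optional epoch selection.
#' @return A `behavior_series` of estimated behavior (`y_est`).
#' @export
estimate_behavior <- function(model, psd, rows = NULL) {
  stopifnot(inherits(model, "spectral_model"), inherits(psd, "psd_timeseries"))
  missing <- setdiff(model$channels, psd$channel_names)
  if (length(missing) > 0L) {
    stop(sprintf("PSD lacks model channel(s): %s", paste(missing, collapse = ", ")))
  }
  if (is.null(rows)) rows <- seq_along(psd$epoch_times)
  X <- stack_features(psd, model$channels, rows = rows)
  Z <- sweep(X, 2L, model$basis$means, "-") %*% model$basis$V
  yhat <- drop(Z %*% model$beta) + model$intercept
  behavior_series(model$metric, psd$epoch_times[rows], yhat,
                  psd$epoch_blocks[rows])
}

#' Fit the standard fixed-montage model
#'
#' Convenience wrapper for the standard modeling scheme: features from the
#' four midline electrodes Fz, Cz, Pz and Oz.
#'
#' @param psd a smoothed `psd_timeseries`.
#' @param y behavioral values aligned to the PSD epochs.
#' @param channels midline montage (default `c("Fz","Cz","Pz","Oz")`).
#' @param rows optional training epoch selection.
#' @param metric metric label.
#' @param threshold explained-variance retention threshold (default 0.01).
#' @return A `spectral_model`.
#' @export
fit_standard <- function(psd, y, channels = c("Fz", "Cz", "Pz", "Oz"),
                         rows = NULL, metric = "behavior", threshold = 0.01) {
  missing <- setdiff(channels, psd$channel_names)
  if (length(missing) > 0L) {
    stop(sprintf("montage lacks channel(s): %s", paste(missing, collapse = ", ")))
  }
  if (is.null(rows)) rows <- seq_along(psd$epoch_times)
  X <- stack_features(psd, channels, rows = rows)
  basis <- fit_basis(X, threshold = threshold)
  fit_model(X, basis, y[rows], metric = metric)
}
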