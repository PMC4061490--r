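#' Per-frequency relative weights of a fitted model
#'
#' Decomposes a fitted model into the relative contribution of each
#' frequency component: for every channel block and frequency, the average
#' training log-power at that channel-frequency column is multiplied by
#' the corresponding entry of each retained eigenvector and by that
#' eigenvector's regression coefficient, summed over the retained
#' components, and normalized by the Euclidean norm of the coefficient
#' vector (so profiles are comparable across models).  The average PSD
#' enters uncentered: the stored column means are used as-is.
#'
#' @param model a `spectral_model`.
#' @param mean_psd optional replacement for the average training log-power
#'   (vector over the model's channel-frequency columns); defaults to the
#'   training means stored in the model.
#' @return An object of class `spectral_weights`: matrix `W`
#'   (channels x frequencies) with the model's channels as row names, plus
#'   `freqs` and `beta_norm`.
#' @export
relative_weights <- function(model, mean_psd = NULL) {
  stopifnot(inherits(model, "spectral_model"))
  if (is.null(mean_psd)) mean_psd <- model$basis$means
  n_f <- length(model$basis$freqs)
  n_ch <- length(model$channels)
  if (length(mean_psd) != n_f * n_ch) stop("mean_psd has the wrong length")
  bnorm <- sqrt(sum(model$beta^2))
  if (bnorm == 0) {
    warning("all regression coefficients are zero; returning a zero profile")
    w_col <- rep(0, n_f * n_ch)
  } else {
    w_col <- mean_psd * drop(model$basis$V %*% model$beta) / bnorm
  }
  W <- t(matrix(w_col, nrow = n_f, ncol = n_ch)) # channels x freqs
  rownames(W) <- model$channels
  colnames(W) <- model$basis$freqs
  structure(list(W = W, freqs = model$basis$freqs, beta_norm = bnorm),
            class = "spectral_weights")
}

#' Aggregate spectral-weight profiles and test them against zero
#'
#' Pools relative-weight profiles across folds and channels (and sessions,
#' when supplied), averages them per frequency, and tests at every
#' frequency whether the pooled weights differ from zero (one-sample
#' t-test) with Benjamini-Hochberg false-discovery-rate control across
#' frequencies.
#'
#' @param profiles list of `spectral_weights` (or plain channels x
#'   frequencies matrices over a common frequency grid).
#' @param alpha FDR level (default 0.05).
#' @return data.frame per frequency: `freq`, `mean_W`, `n`, `p`, `p_adj`,
#'   `significant` (frequencies with fewer than 2 pooled values are
#'   excluded from testing).
#' @export
aggregate_weights <- function(profiles, alpha = 0.05) {
  mats <- lapply(profiles, function(p) if (inherits(p, "spectral_weights")) p$W else p)
  freqs <- colnames(mats[[1]])
  nf <- ncol(mats[[1]])
  if (any(vapply(mats, ncol, 0L) != nf)) stop("profiles use different frequency grids")
  pooled <- lapply(seq_len(nf), function(j) {
    unlist(lapply(mats, function(m) m[, j]), use.names = FALSE)
  })
  mean_W <- vapply(pooled, mean, 0)
  n <- vapply(pooled, length, 0L)
  p <- vapply(pooled, function(v) {
    if (length(v) < 2L || sd(v) == 0) NA_real_ else t.test(v, mu = 0)$p.value
  }, 0)
  testable <- !is.na(p)
  p_adj <- rep(NA_real_, nf)
  p_adj[testable] <- p.adjust(p[testable], method = "BH")
  data.frame(
    freq = if (is.null(freqs)) seq_len(nf) else as.numeric(freqs),
    mean_W = mean_W, n = n, p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha
  )
}

#' Band-average of an aggregated weight profile
#'
#' Convenience summary: the mean of `mean_W` inside a frequency band
#' (inclusive), e.g. theta 4--7 Hz or alpha 8--12 Hz.
#'
#' @param agg output of [aggregate_weights()].
#' @param band numeric length-2 band edges in Hz.
#' @return scalar mean weight in the band.
#' @export
band_weight <- function(agg, band) {
  sel <- agg$freq >= band[1] - 1e-9 & agg$freq <= band[2] + 1e-9
  if (!any(sel)) stop("no frequencies inside the band")
  mean(agg$mean_W[sel])
}
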