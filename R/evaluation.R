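#' Pearson correlation between actual and estimated behavior
#'
#' @param y actual behavior.
#' @param y_est estimated behavior, same length (>= 3).
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(y, y_est) {
  if (length(y) != length(y_est)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 samples")
  if (sd(y) == 0 || sd(y_est) == 0) stop("correlation undefined for constant input")
  cor(y, y_est)
}

#' Normalized root-mean-squared error
#'
#' RMSE between actual and estimated behavior, divided by the standard
#' deviation of the actual behavior (so a constant mean predictor scores
#' approximately 1).
#'
#' @param y actual behavior.
#' @param y_est estimated behavior.
#' @param sd_ref normalizing standard deviation (default `sd(y)`).
#' @return nonnegative scalar.
#' @export
normalized_rmse <- function(y, y_est, sd_ref = sd(y)) {
  if (length(y) != length(y_est)) stop("length mismatch")
  if (sd_ref == 0) stop("sd_ref is zero")
  sqrt(mean((y - y_est)^2)) / sd_ref
}

#' Permutation significance of a behavioral estimate
#'
#' Builds the null distribution of the correlation coefficient by randomly
#' permuting the estimated behavior, re-smoothing the permuted series with
#' the same centered mean filter used throughout the pipeline, and
#' correlating with the actual behavior.  Because low-pass filtered random
#' series attain spuriously large correlations, re-smoothing is essential
#' for a calibrated threshold.  A Gaussian is fit to the permutation
#' correlations to give the significance threshold and p-value
#' (an empirical-quantile threshold is also reported).
#'
#' @param y actual behavior on the epoch grid.
#' @param y_est estimated behavior on the epoch grid.
#' @param times epoch times (seconds).
#' @param block_id block id per epoch (default: one block).
#' @param n_perm number of permutations (default 1000).
#' @param window smoothing width in seconds (default 90).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed (required for reproducibility).
#' @param sided `"one"` (default; a model counts as working only for
#'   positive correlation) or `"two"`.
#' @param block_bounds optional block extents for the smoother.
#' @return list: `r_obs`, `p`, `threshold` (Gaussian), `threshold_empirical`,
#'   `null_mean`, `null_sd`, `null_r` (the permutation draws), `n_perm`,
#'   `alpha`, `sided`, `seed`, `significant`.
#' @export
permutation_significance <- function(y, y_est, times, block_id = NULL,
                                     n_perm = 1000L, window = 90,
                                     alpha = 0.05, seed,
                                     sided = c("one", "two"),
                                     block_bounds = NULL) {
  sided <- match.arg(sided)
  if (missing(seed)) stop("`seed` is required")
  if (n_perm < 100L) warning("fewer than 100 permutations: unstable threshold")
  if (is.null(block_id)) block_id <- rep(1L, length(y))
  r_obs <- pearson_r(y, y_est)
  n <- length(y_est)
  null_r <- numeric(n_perm)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    yp <- y_est[sample.int(n)]
    ys <- smooth_series(yp, times, window = window, block_id = block_id,
                        block_bounds = block_bounds)
    null_r[i] <- if (sd(ys) == 0) 0 else cor(y, ys)
  }
  m <- mean(null_r)
  s <- sd(null_r)
  if (sided == "one") {
    threshold <- m + qnorm(1 - alpha) * s
    thr_emp <- unname(quantile(null_r, 1 - alpha))
    p <- pnorm(r_obs, mean = m, sd = s, lower.tail = FALSE)
  } else {
    threshold <- m + qnorm(1 - alpha / 2) * s
    thr_emp <- unname(quantile(abs(null_r - m), 1 - alpha)) + m
    p <- 2 * pnorm(abs(r_obs - m), mean = 0, sd = s, lower.tail = FALSE)
  }
  list(
    r_obs = r_obs, p = p, threshold = threshold,
    threshold_empirical = thr_emp, null_mean = m, null_sd = s,
    null_r = null_r, n_perm = n_perm, alpha = alpha, sided = sided,
    seed = seed, significant = r_obs > threshold
  )
}

#' Leave-one-block-out cross-validated behavior estimation
#'
#' For each experimental block, a model is built from the remaining blocks
#' (for the adaptive scheme this includes running SFFS channel selection on
#' the training blocks only) and used to predict the held-out block.  The
#' per-fold predictions are assembled into a full-session estimate, which
#' is scored by Pearson correlation, normalized RMSE and permutation
#' significance.  Because both the PSD and the behavior are smoothed
#' strictly within blocks, training and testing sets are temporally
#' separated by at least the smoothing window.
#'
#' @param psd a smoothed `psd_timeseries` with `epoch_blocks` set.
#' @param y behavioral values aligned to the PSD epochs, or a
#'   `behavior_series`.
#' @param scheme `"adaptive"` (SFFS channel selection) or `"standard"`
#'   (fixed midline montage).
#' @param standard_channels montage for the standard scheme.
#' @param candidates candidate channels for the adaptive scheme (default:
#'   all).
#' @param metric metric label for the fitted models.
#' @param protocol SFFS criterion protocol, see [criterion_J()].
#' @param k_max,max_iter SFFS limits (defaults 12 and 500).
#' @param threshold explained-variance retention threshold.
#' @param n_perm,alpha,sided permutation-test settings.
#' @param window smoothing width (seconds) used when re-smoothing permuted
#'   estimates.
#' @param seed RNG seed for the permutation test.
#' @return An object of class `cv_result`: per-fold `models` (and
#'   `sffs` results for the adaptive scheme), `y`, `y_est`, `times`,
#'   `blocks`, overall `R`, `per_block_R`, `nrmse`, `significance`.
#' @export
loo_block_cv <- function(psd, y, scheme = c("adaptive", "standard"),
                         standard_channels = c("Fz", "Cz", "Pz", "Oz"),
                         candidates = NULL, metric = "behavior",
                         protocol = "inner-cv", k_max = 12L, max_iter = 500L,
                         threshold = 0.01, n_perm = 1000L, alpha = 0.05,
                         sided = "one", window = 90, seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(y, "behavior_series")) y <- align_behavior(y, psd)
  if (anyNA(y)) stop("behavior could not be aligned to every epoch")
  engine <- build_engine(psd, y)
  blocks <- engine$block_ids
  if (length(blocks) < 2L) stop("need at least 2 blocks for cross-validation")
  for (b in blocks) {
    if (length(engine$rows_by_block[[as.character(b)]]) == 0L) {
      stop(sprintf("block %s has no epochs", b))
    }
  }
  if (scheme == "standard") {
    miss <- setdiff(standard_channels, engine$channel_names)
    if (length(miss) > 0L) {
      stop(sprintf("montage lacks channel(s): %s", paste(miss, collapse = ", ")))
    }
  }

  y_est <- rep(NA_real_, length(y))
  models <- list()
  sffs_results <- list()
  for (b in blocks) {
    train <- setdiff(blocks, b)
    rows_te <- engine$rows_by_block[[as.character(b)]]
    if (scheme == "adaptive") {
      sel <- sffs_select(candidates = candidates, train_blocks = train,
                         k_max = k_max, max_iter = max_iter,
                         protocol = protocol, threshold = threshold,
                         engine = engine)
      sffs_results[[as.character(b)]] <- sel
      ch_idx <- match(sel$best_subset, engine$channel_names)
    } else {
      ch_idx <- match(standard_channels, engine$channel_names)
    }
    fit <- engine_fit(engine, ch_idx, train, threshold = threshold)
    y_est[rows_te] <- engine_predict(engine, fit, rows_te)
    models[[as.character(b)]] <- as_spectral_model(engine, fit, metric = metric)
  }

  R <- pearson_r(y, y_est)
  per_block_R <- vapply(blocks, function(b) {
    r <- engine$rows_by_block[[as.character(b)]]
    if (sd(y[r]) == 0 || sd(y_est[r]) == 0) NA_real_ else cor(y[r], y_est[r])
  }, 0)
  names(per_block_R) <- as.character(blocks)
  sig <- permutation_significance(
    y, y_est, engine$times, block_id = engine$blocks_vec,
    n_perm = n_perm, window = window, alpha = alpha, seed = seed, sided = sided
  )
  structure(
    list(
      scheme = scheme, metric = metric, models = models, sffs = sffs_results,
      y = y, y_est = y_est, times = engine$times, blocks = engine$blocks_vec,
      R = R, per_block_R = per_block_R,
      nrmse = normalized_rmse(y, y_est), significance = sig
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s scheme, metric '%s': R = %.3f (threshold %.3f, p = %.3g), nRMSE = %.3f\n",
    x$scheme, x$metric, x$R, x$significance$threshold, x$significance$p, x$nrmse
  ))
  invisible(x)
}

#' Apply cross-validated models to the alternate task
#'
#' Each per-fold model from task A produces a full-session estimate of the
#' task-B behavior; a least-squares slope-and-offset rescale maps the
#' estimate onto the new metric's scale (this corrects sign and scale but
#' cannot change the magnitude of the correlation).  Per-model correlations
#' are reported with their mean and standard error.
#'
#' @param models list of `spectral_model`s (the per-fold models from the
#'   cross-validation on the source task).
#' @param psd_b smoothed `psd_timeseries` of the target task.
#' @param y_b target-task behavior (`behavior_series` or vector aligned to
#'   `psd_b` epochs).
#' @return list: `per_model_R`, `mean_R`, `se_R`, `estimates` (rescaled),
#'   `slopes`, `offsets`, `times`, `y`.
#' @export
cross_task_transfer <- function(models, psd_b, y_b) {
  if (inherits(y_b, "behavior_series")) y_b <- align_behavior(y_b, psd_b)
  if (anyNA(y_b)) stop("behavior could not be aligned to every epoch")
  per_R <- numeric(0)
  ests <- list()
  slopes <- numeric(0)
  offsets <- numeric(0)
  for (nm in names(models)) {
    model <- models[[nm]]
    if (length(setdiff(model$channels, psd_b$channel_names)) > 0L) {
      warning(sprintf("model %s skipped: channel mismatch", nm))
      next
    }
    est <- estimate_behavior(model, psd_b)$values
    r <- pearson_r(y_b, est)
    cf <- stats::coef(stats::lm(y_b ~ est))
    ests[[nm]] <- unname(cf[1] + cf[2] * est)
    slopes[nm] <- unname(cf[2])
    offsets[nm] <- unname(cf[1])
    per_R[nm] <- r
  }
  if (length(per_R) == 0L) stop("no model could be applied")
  list(
    per_model_R = per_R, mean_R = mean(per_R),
    se_R = sd(per_R) / sqrt(length(per_R)),
    estimates = ests, slopes = slopes, offsets = offsets,
    times = psd_b$epoch_times, y = y_b
  )
}
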