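#' Build the smoothed RSVP behavior series from events and presses
#'
#' Runs press-to-image assignment, optional per-image grand-average
#' normalization, optional block-wise target-probability adjustment (RT
#' and duration only), trial placement at target onsets and the centered
#' mean smoothing.
#'
#' @param events,presses RSVP event stream and button presses (see
#'   [assign_presses()]).
#' @param metric `"accuracy"`, `"rt"` or `"duration"`.
#' @param grand_avg optional grand-average table from
#'   [grand_average_table()]; when supplied the trial values are
#'   normalized against it.
#' @param adjust_probability remove the block target-probability effect
#'   from RT/duration (default TRUE).
#' @param window smoothing width in seconds.
#' @param block_bounds optional block extents.
#' @return A `behavior_series`.
#' @export
rsvp_behavior <- function(events, presses, metric, grand_avg = NULL,
                          adjust_probability = TRUE, window = 90,
                          block_bounds = NULL) {
  metric <- match.arg(metric, c("accuracy", "rt", "duration"))
  asg <- assign_presses(events, presses)
  out <- asg$target_outcomes
  col <- c(accuracy = "hit", rt = "rt_ms", duration = "duration_ms")[[metric]]
  if (!is.null(grand_avg)) {
    ok <- if (metric == "accuracy") rep(TRUE, nrow(out)) else out$hit == 1
    out[[col]][ok] <- normalize_behavior(out[[col]][ok], out$image_id[ok],
                                         grand_avg, metric)
  }
  if (adjust_probability && metric %in% c("rt", "duration")) {
    prob_by_block <- tapply(events$target_prob, events$block_id, function(x) x[1])
    bp <- prob_by_block[as.character(out$block_id)]
    ok <- out$hit == 1
    out[[col]][ok] <- adjust_for_probability(out[[col]][ok], metric, bp[ok])
  }
  rsvp_metric_series(out, metric, window = window, block_bounds = block_bounds)
}

#' Run the full estimation pipeline on a simulated session
#'
#' Preprocessing is not needed for simulated sessions (generated at the
#' target rate); the pipeline computes the block-wise PSD, smooths it,
#' builds the requested behavioral series, runs the chosen modeling scheme
#' under leave-one-block-out cross-validation with permutation
#' significance, and decomposes the per-fold models into spectral
#' weights.
#'
#' @param session output of [simulate_session()] (or a compatible list
#'   with `eeg`, `blocks`, and `vehicle_log`/`rsvp` entries).
#' @param metric `"lane_dev"`, `"accuracy"`, `"rt"` or `"duration"`.
#' @param scheme `"adaptive"` or `"standard"`.
#' @param window smoothing width in seconds (default 90).
#' @param grand_avg optional grand-average table for RSVP normalization.
#' @param psd_args list of overrides passed to [compute_psd_blocks()].
#' @param seed RNG seed for the permutation test (default: the session
#'   seed).
#' @param ... further arguments passed to [loo_block_cv()].
#' @return list: `psd` (smoothed), `behavior`, `y`, `cv` (a `cv_result`),
#'   `weights` (aggregated per-frequency table), `profiles`.
#' @export
run_pipeline <- function(session, metric = "lane_dev",
                         scheme = c("adaptive", "standard"), window = 90,
                         grand_avg = NULL, psd_args = list(), seed = NULL,
                         ...) {
  scheme <- match.arg(scheme)
  if (is.null(seed)) seed <- if (!is.null(session$seed)) session$seed else 1L
  blocks <- session$blocks
  psd <- do.call(compute_psd_blocks, c(list(session$eeg, blocks), psd_args))
  psd <- smooth_psd(psd, window = window, block_bounds = blocks)
  if (metric == "lane_dev") {
    if (is.null(session$vehicle_log)) stop("session has no vehicle log")
    behavior <- lane_deviation_series(session$vehicle_log, window = window,
                                      block_bounds = blocks)
  } else {
    if (is.null(session$rsvp)) stop("session has no RSVP stream")
    behavior <- rsvp_behavior(session$rsvp$events, session$rsvp$presses,
                              metric, grand_avg = grand_avg,
                              window = window, block_bounds = blocks)
  }
  y <- align_behavior(behavior, psd)
  cv <- loo_block_cv(psd, y, scheme = scheme, metric = metric,
                     window = window, seed = seed, ...)
  profiles <- lapply(cv$models, relative_weights)
  weights <- aggregate_weights(profiles)
  list(psd = psd, behavior = behavior, y = y, cv = cv,
       weights = weights, profiles = profiles)
}

#' Compact JSON-ready summary of a cross-validation result
#'
#' @param cv a `cv_result`.
#' @return list of scalars/vectors suitable for `jsonlite::write_json`.
#' @export
cv_report <- function(cv) {
  list(
    scheme = cv$scheme, metric = cv$metric,
    overall_R = cv$R, per_block_R = as.list(cv$per_block_R),
    nrmse = cv$nrmse, p = cv$significance$p,
    threshold = cv$significance$threshold,
    n_perm = cv$significance$n_perm, seed = cv$significance$seed,
    significant = cv$significance$significant,
    subset_sizes = if (length(cv$sffs) > 0) {
      vapply(cv$sffs, function(s) length(s$best_subset), 0L)
    } else NULL
  )
}
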