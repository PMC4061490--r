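#' Behavioral time series
#'
#' A behavioral metric on a time grid, alignable to PSD epochs.
#'
#' @param metric one of `"lane_dev"`, `"accuracy"`, `"rt"`, `"duration"`
#'   (free-form labels are allowed).
#' @param times sample times in seconds.
#' @param values metric values.
#' @param blocks block id per sample.
#' @param units unit label (`"m"`, `"ms"` or `""`).
#' @return An object of class `behavior_series`.
#' @export
behavior_series <- function(metric, times, values, blocks = NULL, units = "") {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (is.null(blocks)) blocks <- rep(1L, length(times))
  structure(
    list(metric = metric, times = as.numeric(times), values = as.numeric(values),
         blocks = as.integer(blocks), units = units),
    class = "behavior_series"
  )
}

#' @export
print.behavior_series <- function(x, ...) {
  cat(sprintf(
    "<behavior_series> %s [%s]: %d samples, %d block(s)\n",
    x$metric, x$units, length(x$values), length(unique(x$blocks))
  ))
  invisible(x)
}

#' Resample a behavior series onto the PSD epoch grid
#'
#' Nearest-time lookup within the same block; epochs in blocks absent from
#' the behavior series get `NA`.
#'
#' @param behavior a `behavior_series`.
#' @param psd a `psd_timeseries`.
#' @return numeric vector, one value per PSD epoch.
#' @export
align_behavior <- function(behavior, psd) {
  out <- rep(NA_real_, length(psd$epoch_times))
  for (b in unique(psd$epoch_blocks)) {
    esel <- which(psd$epoch_blocks == b)
    bsel <- which(behavior$blocks == b)
    if (length(bsel) == 0L) next
    tt <- behavior$times[bsel]
    et <- psd$epoch_times[esel]
    j <- findInterval(et, tt)
    j_lo <- pmax(j, 1L)
    j_hi <- pmin(j + 1L, length(tt))
    pick <- ifelse(abs(et - tt[j_lo]) <= abs(tt[j_hi] - et), j_lo, j_hi)
    out[esel] <- behavior$values[bsel][pick]
  }
  out
}

#' Smoothed absolute lane deviation series
#'
#' Driving performance metric: the absolute lateral deviation from the lane
#' center, smoothed per block with the centered mean filter.
#'
#' @param log data.frame vehicle log with columns `t`, `lane_offset`,
#'   `block_id` (times in seconds, offsets in meters).
#' @param window smoothing width in seconds (default 90).
#' @param block_bounds optional block extents (see [smooth_series()]).
#' @return A `behavior_series` with metric `"lane_dev"`.
#' @export
lane_deviation_series <- function(log, window = 90, block_bounds = NULL) {
  if (nrow(log) == 0L) stop("empty vehicle log")
  dev <- abs(log$lane_offset)
  sm <- smooth_series(dev, log$t, window = window, block_id = log$block_id,
                      block_bounds = block_bounds)
  behavior_series("lane_dev", log$t, sm, log$block_id, units = "m")
}

#' Assign button presses to RSVP images
#'
#' For each press, images with onset between 1000 and 300 ms before the
#' press are candidates.  If one or more candidates is a target, the press
#' is assigned to the earliest (oldest) unclaimed target and the reaction
#' time is measured from that image's onset.  Otherwise the press is a
#' false alarm, attributed to the non-target image whose onset is nearest
#' to 600 ms before the press (no RT recorded).  Targets never claimed by
#' any press are misses.  Presses are processed in temporal order, so an
#' earlier press claims a shared target and the result does not depend on
#' input ordering.
#'
#' @param events data.frame of image events: `t_onset_s`, `image_id`,
#'   `is_target`, `block_id`.
#' @param presses data.frame of button presses: `press_on_s`, `press_off_s`.
#' @param window RT window in seconds before the press (default
#'   `c(0.3, 1.0)`, boundaries inclusive).
#' @param fa_lag assumed RT for false-alarm attribution, seconds (0.6).
#' @return list with `responses` (one row per press: assigned image,
#'   target flag, RT in ms for target assignments, press duration in ms)
#'   and `target_outcomes` (one row per target image instance: hit
#'   indicator, RT and duration for hits).
#' @export
assign_presses <- function(events, presses, window = c(0.3, 1.0), fa_lag = 0.6) {
  ev <- events[order(events$t_onset_s), , drop = FALSE]
  is_img <- if ("is_blink" %in% names(ev)) !ev$is_blink else rep(TRUE, nrow(ev))
  ev <- ev[is_img, , drop = FALSE]
  pr <- presses[order(presses$press_on_s), , drop = FALSE]
  n_pr <- nrow(pr)
  tgt_idx <- which(ev$is_target)
  claimed <- rep(FALSE, length(tgt_idx))
  tgt_times <- ev$t_onset_s[tgt_idx]
  nt_idx <- which(!ev$is_target)
  nt_times <- ev$t_onset_s[nt_idx]

  res <- data.frame(
    press_on_s = pr$press_on_s, press_off_s = pr$press_off_s,
    image_id = NA_character_, assigned_target = FALSE,
    rt_ms = NA_real_, duration_ms = (pr$press_off_s - pr$press_on_s) * 1000,
    block_id = NA_integer_, assigned = FALSE,
    stringsAsFactors = FALSE
  )
  claimed_by <- rep(NA_integer_, length(tgt_idx)) # press row per target

  eps <- 1e-9
  for (i in seq_len(n_pr)) {
    p <- pr$press_on_s[i]
    lo <- p - window[2] - eps
    hi <- p - window[1] + eps
    cand <- which(tgt_times >= lo & tgt_times <= hi & !claimed)
    if (length(cand) > 0L) {
      k <- cand[1] # earliest (oldest) unclaimed target
      claimed[k] <- TRUE
      claimed_by[k] <- i
      row <- tgt_idx[k]
      res$image_id[i] <- as.character(ev$image_id[row])
      res$assigned_target[i] <- TRUE
      res$rt_ms[i] <- (p - tgt_times[k]) * 1000
      res$block_id[i] <- ev$block_id[row]
      res$assigned[i] <- TRUE
    } else {
      if (length(nt_times) == 0L || p < min(ev$t_onset_s) + window[1] - eps) next
      k <- which.min(abs(nt_times - (p - fa_lag)))
      row <- nt_idx[k]
      res$image_id[i] <- as.character(ev$image_id[row])
      res$block_id[i] <- ev$block_id[row]
      res$assigned[i] <- TRUE
    }
  }

  hit <- claimed
  target_outcomes <- data.frame(
    t_onset_s = tgt_times,
    image_id = as.character(ev$image_id[tgt_idx]),
    block_id = ev$block_id[tgt_idx],
    hit = as.numeric(hit),
    rt_ms = ifelse(hit, res$rt_ms[claimed_by], NA_real_),
    duration_ms = ifelse(hit, res$duration_ms[claimed_by], NA_real_),
    stringsAsFactors = FALSE
  )
  n_unassigned <- sum(!res$assigned)
  if (n_unassigned > 0L) {
    message(sprintf("%d press(es) could not be assigned to any image", n_unassigned))
  }
  list(responses = res, target_outcomes = target_outcomes)
}

#' Grand-average behavior per target image
#'
#' Mean accuracy, RT and press duration for each target image across a set
#' of participants' response tables, used by [normalize_behavior()] to
#' remove per-image perceptual difficulty.
#'
#' @param outcome_list list of `target_outcomes` data.frames from
#'   [assign_presses()] (one per participant).
#' @return data.frame: `image_id`, `accuracy`, `rt_ms`, `duration_ms`,
#'   `n`.
#' @export
grand_average_table <- function(outcome_list) {
  all <- do.call(rbind, outcome_list)
  sp <- split(all, all$image_id)
  out <- data.frame(
    image_id = names(sp),
    accuracy = vapply(sp, function(d) mean(d$hit), 0),
    rt_ms = vapply(sp, function(d) if (any(d$hit == 1)) mean(d$rt_ms[d$hit == 1]) else NA_real_, 0),
    duration_ms = vapply(sp, function(d) if (any(d$hit == 1)) mean(d$duration_ms[d$hit == 1]) else NA_real_, 0),
    n = vapply(sp, nrow, 0L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Normalize trial-level behavior against the per-image grand average
#'
#' Subtracts the grand-average response for the same target image and
#' re-anchors at a nominal value: 1 for accuracy, 600 ms for RT, 300 ms for
#' press duration.  Values above the nominal mean better-than-average
#' accuracy, or slower/longer-than-average RT/duration, for that image.
#'
#' @param values trial-level metric values.
#' @param image_ids target image id per trial.
#' @param grand_avg grand-average table from [grand_average_table()].
#' @param metric `"accuracy"`, `"rt"` or `"duration"`.
#' @param nominal named nominal values (defaults: accuracy 1, rt 600,
#'   duration 300).
#' @return numeric vector of normalized values.
#' @export
normalize_behavior <- function(values, image_ids, grand_avg, metric,
                               nominal = c(accuracy = 1, rt = 600, duration = 300)) {
  metric <- match.arg(metric, c("accuracy", "rt", "duration"))
  col <- c(accuracy = "accuracy", rt = "rt_ms", duration = "duration_ms")[[metric]]
  m <- match(as.character(image_ids), grand_avg$image_id)
  if (anyNA(m)) {
    stop(sprintf(
      "image(s) missing from the grand-average table: %s",
      paste(unique(image_ids[is.na(m)])[1:min(3, sum(is.na(m)))], collapse = ", ")
    ))
  }
  ga <- grand_avg[[col]][m]
  unname(nominal[[metric]] + (values - ga))
}

#' Remove the target-probability effect from RT or press duration
#'
#' RT and press duration decrease approximately linearly with the block's
#' target probability (fitted slopes of -262 ms and -277 ms per unit
#' probability).  This removes the fitted linear effect by subtracting
#' `slope * (p - reference)` block by block; accuracy is never adjusted.
#'
#' @param values trial-level metric values (ms).
#' @param metric `"rt"` or `"duration"`.
#' @param block_probability target probability of each trial's block.
#' @param slope ms per unit probability (defaults: rt -262, duration -277).
#' @param reference reference probability the series is anchored to
#'   (default 0.06, the mean of the block probabilities used in a session).
#' @return adjusted values.
#' @export
adjust_for_probability <- function(values, metric, block_probability,
                                   slope = NULL, reference = 0.06) {
  metric <- match.arg(metric, c("rt", "duration"))
  if (any(block_probability <= 0 | block_probability >= 1)) {
    stop("block probabilities must lie in (0, 1)")
  }
  if (is.null(slope)) slope <- c(rt = -262, duration = -277)[[metric]]
  values - slope * (block_probability - reference)
}

#' Smoothed RSVP behavioral metric series
#'
#' Places trial-level values at target-image onset times (accuracy: hit = 1
#' / miss = 0 for every target; RT and duration: hits only) and applies the
#' centered mean filter per block on that irregular grid.
#'
#' @param target_outcomes `target_outcomes` from [assign_presses()], with
#'   optionally normalized/adjusted metric columns.
#' @param metric `"accuracy"`, `"rt"` or `"duration"`.
#' @param window smoothing width in seconds (default 90).
#' @param block_bounds optional block extents (see [smooth_series()]).
#' @return A `behavior_series`.
#' @export
rsvp_metric_series <- function(target_outcomes, metric, window = 90,
                               block_bounds = NULL) {
  metric <- match.arg(metric, c("accuracy", "rt", "duration"))
  col <- c(accuracy = "hit", rt = "rt_ms", duration = "duration_ms")[[metric]]
  d <- target_outcomes
  if (metric != "accuracy") d <- d[d$hit == 1, , drop = FALSE]
  if (nrow(d) == 0L) stop("no trials available for this metric")
  empty <- setdiff(unique(target_outcomes$block_id), unique(d$block_id))
  if (length(empty) > 0L) {
    message("blocks without usable trials: ", paste(empty, collapse = ", "))
  }
  d <- d[order(d$block_id, d$t_onset_s), , drop = FALSE]
  sm <- smooth_series(d[[col]], d$t_onset_s, window = window,
                      block_id = d$block_id, block_bounds = block_bounds)
  units <- if (metric == "accuracy") "" else "ms"
  behavior_series(metric, d$t_onset_s, sm, d$block_id, units = units)
}

#' Within-block linear trend detection
#'
#' Ordinary least squares of a behavioral metric against time within each
#' block, with a t-test on the slope.  A reporting aid for counting blocks
#' with significant time-on-task decrements; not part of the estimation
#' path.
#'
#' @param behavior a `behavior_series` (typically unsmoothed trial values).
#' @param alpha significance level (default 0.05).
#' @return data.frame per block: `block`, `slope`, `p`, `significant`.
#' @export
block_trends <- function(behavior, alpha = 0.05) {
  res <- lapply(unique(behavior$blocks), function(b) {
    sel <- behavior$blocks == b
    t <- behavior$times[sel]
    v <- behavior$values[sel]
    if (length(v) < 3L || sd(v) == 0) {
      return(data.frame(block = b, slope = NA_real_, p = NA_real_, significant = FALSE))
    }
    fit <- summary(stats::lm(v ~ t))
    sl <- fit$coefficients["t", ]
    data.frame(block = b, slope = sl[["Estimate"]], p = sl[["Pr(>|t|)"]],
               significant = sl[["Pr(>|t|)"]] < alpha)
  })
  do.call(rbind, res)
}
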