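#' Log power spectral density time series
#'
#' Container for the per-channel log10 power spectrum on an epoch time grid.
#'
#' @param logpower numeric array, epochs x channels x frequencies.
#' @param freqs frequency bin centers in Hz.
#' @param epoch_times epoch center times in seconds (strictly increasing
#'   within a block).
#' @param channel_names channel labels.
#' @param epoch_blocks integer block id per epoch (default all 1).
#' @return An object of class `psd_timeseries`.
#' @export
psd_timeseries <- function(logpower, freqs, epoch_times, channel_names,
                           epoch_blocks = NULL) {
  stopifnot(length(dim(logpower)) == 3L)
  if (dim(logpower)[1] != length(epoch_times)) stop("epoch_times length mismatch")
  if (dim(logpower)[2] != length(channel_names)) stop("channel_names length mismatch")
  if (dim(logpower)[3] != length(freqs)) stop("freqs length mismatch")
  if (anyNA(logpower)) stop("logpower contains NA")
  if (is.null(epoch_blocks)) epoch_blocks <- rep(1L, length(epoch_times))
  structure(
    list(
      logpower = logpower, freqs = freqs, epoch_times = as.numeric(epoch_times),
      channel_names = as.character(channel_names),
      epoch_blocks = as.integer(epoch_blocks)
    ),
    class = "psd_timeseries"
  )
}

#' @export
print.psd_timeseries <- function(x, ...) {
  cat(sprintf(
    "<psd_timeseries> %d epochs x %d channels x %d freqs (%g-%g Hz), %d block(s)\n",
    dim(x$logpower)[1], dim(x$logpower)[2], dim(x$logpower)[3],
    min(x$freqs), max(x$freqs), length(unique(x$epoch_blocks))
  ))
  invisible(x)
}

#' Compute the log power spectral density time series
#'
#' Sliding-epoch PSD estimation: each epoch is subdivided into Hann-windowed
#' segments; each segment's power spectrum is computed by zero-padded FFT; a
#' sliding median filter across segments suppresses transient artifacts; the
#' filtered spectra are averaged over segments and converted to log10.
#' With the defaults at 256 Hz this yields ~3 s epochs every ~2 s, 26
#' segments per epoch, and a 1 Hz bin grid restricted to 1--40 Hz.
#'
#' @param eeg a preprocessed `eeg_recording`.
#' @param epoch_len epoch length in samples (default 750).
#' @param epoch_step epoch step in samples (default 500).
#' @param win_len segment length in samples (default 125).
#' @param win_step segment step in samples (default 25).
#' @param nfft FFT length after zero-padding (default 256).
#' @param median_order odd order of the median filter across segments
#'   (default 5; shrunk symmetrically at epoch edges).
#' @param freq_range frequencies to keep, Hz (default `c(1, 40)`).
#' @return A `psd_timeseries`.
#' @export
compute_psd <- function(eeg, epoch_len = 750L, epoch_step = 500L,
                        win_len = 125L, win_step = 25L, nfft = 256L,
                        median_order = 5L, freq_range = c(1, 40)) {
  stopifnot(inherits(eeg, "eeg_recording"))
  n <- ncol(eeg$data)
  if (n < epoch_len) stop("signal shorter than one epoch")
  if (median_order %% 2L == 0L) stop("`median_order` must be odd")
  if (win_len > nfft) stop("`win_len` must not exceed `nfft`")
  fs <- eeg$fs
  n_epoch <- (n - epoch_len) %/% epoch_step + 1L
  nwin <- (epoch_len - win_len) %/% win_step + 1L

  bin_freq <- (0:(nfft %/% 2L)) * fs / nfft
  keep <- which(bin_freq >= freq_range[1] - 1e-9 & bin_freq <= freq_range[2] + 1e-9)
  if (length(keep) == 0L) stop("no FFT bins inside `freq_range`")
  freqs <- bin_freq[keep]
  n_freq <- length(freqs)

  # direct DFT of Hann-windowed segments at the kept bins only, via two
  # small matrix products (the zero-padding only sets the bin grid)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win_len - 1L)) / (win_len - 1L))
  ang <- outer(keep - 1L, 0:(win_len - 1L)) * (2 * pi / nfft)
  Cb <- cos(ang) * rep(hann, each = n_freq)
  Sb <- sin(ang) * rep(hann, each = n_freq)

  epoch_start <- (seq_len(n_epoch) - 1L) * epoch_step # 0-based
  win_offsets <- (seq_len(nwin) - 1L) * win_step
  ws <- outer(win_offsets, epoch_start, "+") # nwin x n_epoch, 0-based
  ustarts <- sort(unique(as.vector(ws)))
  wmap <- matrix(match(as.vector(ws), ustarts), nwin, n_epoch)
  seg_idx <- outer(seq_len(win_len), ustarts, "+") # 1-based sample indices

  n_ch <- nrow(eeg$data)
  logpower <- array(0, dim = c(n_epoch, n_ch, n_freq))
  storage.mode(wmap) <- "integer"
  for (ch in seq_len(n_ch)) {
    seg <- matrix(eeg$data[ch, ][seg_idx], nrow = win_len)
    p_all <- (Cb %*% seg)^2 + (Sb %*% seg)^2 # n_freq x n_ustarts
    avg <- .Call(C_psd_medavg, p_all, wmap, as.integer(median_order))
    logpower[, ch, ] <- t(log10(pmax(avg, .Machine$double.xmin)))
  }

  epoch_times <- eeg$t0 + (epoch_start + epoch_len / 2) / fs
  psd_timeseries(logpower, freqs, epoch_times, eeg$channel_names)
}

#' Compute the PSD block by block
#'
#' Splits the recording at block boundaries, computes the PSD within each
#' block (epochs never straddle a boundary) and concatenates the results
#' with per-epoch block labels.
#'
#' @param eeg an `eeg_recording` spanning the session.
#' @param blocks data.frame with columns `block`, `start`, `end` (seconds,
#'   half-open intervals).
#' @param ... further arguments passed to [compute_psd()].
#' @return A `psd_timeseries` with `epoch_blocks` set.
#' @export
compute_psd_blocks <- function(eeg, blocks, ...) {
  stopifnot(inherits(eeg, "eeg_recording"))
  tt <- eeg_times(eeg)
  pieces <- lapply(seq_len(nrow(blocks)), function(i) {
    sel <- which(tt >= blocks$start[i] - 1e-9 & tt < blocks$end[i] - 1e-9)
    if (length(sel) == 0L) stop(sprintf("block %s contains no samples", blocks$block[i]))
    sub <- eeg_recording(eeg$data[, sel, drop = FALSE], eeg$fs,
                         eeg$channel_names, t0 = tt[sel[1]])
    p <- compute_psd(sub, ...)
    p$epoch_blocks <- rep(as.integer(blocks$block[i]), length(p$epoch_times))
    p
  })
  out <- pieces[[1]]
  if (length(pieces) > 1L) {
    out$logpower <- do.call(abind1, lapply(pieces, `[[`, "logpower"))
    out$epoch_times <- unlist(lapply(pieces, `[[`, "epoch_times"))
    out$epoch_blocks <- unlist(lapply(pieces, `[[`, "epoch_blocks"))
  }
  out
}

# bind 3-d arrays along dim 1
abind1 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  n1 <- sum(vapply(args, function(a) dim(a)[1], 0L))
  out <- array(0, dim = c(n1, d[2], d[3]))
  at <- 0L
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# Windowed mean of the columns of M over an irregular time grid, with the
# edge-padding rule: points whose full +/- window/2 support lies inside the
# block keep their windowed mean; points nearer an edge are replaced by the
# nearest such "valid" value.  If no point is valid (block shorter than the
# window) the clipped-window means are kept.
smooth_matrix_block <- function(M, times, window, bstart, bend) {
  n <- nrow(M)
  if (n == 0L) return(M)
  half <- window / 2
  eps <- 1e-9
  j_lo <- findInterval(times - half - eps, times) + 1L
  j_hi <- findInterval(times + half + eps, times)
  cs <- rbind(0, apply(M, 2L, cumsum))
  cnt <- j_hi - j_lo + 1L
  sm <- (cs[j_hi + 1L, , drop = FALSE] - cs[j_lo, , drop = FALSE]) / cnt
  valid <- times >= bstart + half - eps & times <= bend - half + eps
  if (any(valid)) {
    first <- which(valid)[1]
    last <- which(valid)[sum(valid)]
    if (first > 1L) sm[seq_len(first - 1L), ] <- rep(sm[first, ], each = first - 1L)
    if (last < n) sm[seq(last + 1L, n), ] <- rep(sm[last, ], each = n - last)
  }
  sm
}

#' Centered mean smoothing with block-aware edge padding
#'
#' Smooths a time series with a centered mean filter of fixed temporal
#' width.  Each point whose full window lies inside its block is replaced
#' by the mean of all samples within half a window on either side; points
#' closer to a block edge are padded with the first/last valid smoothed
#' value.  The filter is applied per block and never mixes samples across
#' block boundaries.
#'
#' @param values numeric vector.
#' @param times sample times in seconds, increasing within each block.
#' @param window filter width in seconds (default 90).
#' @param block_id optional block label per sample (default: one block).
#' @param block_bounds optional data.frame (`block`, `start`, `end`) giving
#'   true block extents; defaults to the observed time range per block.
#' @return numeric vector of smoothed values.
#' @export
smooth_series <- function(values, times, window = 90, block_id = NULL,
                          block_bounds = NULL) {
  if (length(values) == 0L) stop("empty input")
  if (length(values) != length(times)) stop("values/times length mismatch")
  if (window <= 0) stop("`window` must be positive")
  if (is.null(block_id)) block_id <- rep(1L, length(values))
  out <- numeric(length(values))
  for (b in unique(block_id)) {
    sel <- which(block_id == b)
    tt <- times[sel]
    if (is.unsorted(tt)) stop("times must be increasing within a block")
    if (!is.null(block_bounds)) {
      row <- match(b, block_bounds$block)
      bstart <- block_bounds$start[row]
      bend <- block_bounds$end[row]
    } else {
      bstart <- tt[1]
      bend <- tt[length(tt)]
    }
    out[sel] <- smooth_matrix_block(
      matrix(values[sel], ncol = 1L), tt, window, bstart, bend
    )
  }
  out
}

#' Smooth a PSD time series in time
#'
#' Applies the centered mean filter of [smooth_series()] to every
#' channel-frequency log-power series, per block.
#'
#' @param psd a `psd_timeseries`.
#' @param window filter width in seconds (default 90).
#' @param block_bounds optional block extents as in [smooth_series()].
#' @return A smoothed `psd_timeseries`.
#' @export
smooth_psd <- function(psd, window = 90, block_bounds = NULL) {
  stopifnot(inherits(psd, "psd_timeseries"))
  d <- dim(psd$logpower)
  flat <- matrix(psd$logpower, nrow = d[1]) # epochs x (channels*freqs)
  for (b in unique(psd$epoch_blocks)) {
    sel <- which(psd$epoch_blocks == b)
    tt <- psd$epoch_times[sel]
    if (!is.null(block_bounds)) {
      row <- match(b, block_bounds$block)
      bstart <- block_bounds$start[row]
      bend <- block_bounds$end[row]
    } else {
      bstart <- tt[1]
      bend <- tt[length(tt)]
    }
    flat[sel, ] <- smooth_matrix_block(flat[sel, , drop = FALSE], tt, window,
                                       bstart, bend)
  }
  psd$logpower <- array(flat, dim = d)
  psd
}
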