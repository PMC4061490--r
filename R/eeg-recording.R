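#' EEG recording container
#'
#' A minimal container for a multichannel EEG time series: a channels-by-
#' samples numeric matrix, a sampling rate, ordered channel labels and a
#' session start time.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of unique labels, one per row.
#' @param t0 session time of the first sample, seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) stop("`fs` must be a single positive number")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per row of `data`")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (is.null(rownames(data))) {
    dimnames(data) <- list(channel_names, NULL)
  }
  structure(
    list(data = data, fs = fs, channel_names = channel_names, t0 = t0),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$t0
  ))
  invisible(x)
}

#' Sample times of an EEG recording
#' @param eeg an `eeg_recording`.
#' @return numeric vector of per-sample session times in seconds.
#' @export
eeg_times <- function(eeg) {
  eeg$t0 + (seq_len(ncol(eeg$data)) - 1L) / eeg$fs
}

#' Channel labels of the 32-channel BioSemi montage
#'
#' The fixed montage that down-selected high-density recordings are mapped
#' onto, and the candidate pool for adaptive channel selection.  Includes
#' the four midline electrodes (Fz, Cz, Pz, Oz) used by the standard
#' modeling scheme.
#'
#' @return character vector of 32 channel labels.
#' @export
biosemi32_channels <- function() {
  c(
    "Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz"
  )
}

#' Down-select a montage by neighborhood averaging
#'
#' Maps a (typically high-density) recording onto a smaller montage.  Each
#' output channel is the arithmetic mean of a set of source channels: the
#' matching electrode plus its directly adjacent neighbors.  Averaging over
#' the neighborhood mitigates noise or high impedance on any single lead.
#'
#' @param eeg an `eeg_recording`.
#' @param montage named list: output label -> character vector of source
#'   labels to average.
#' @return An `eeg_recording` with one channel per montage entry, in
#'   montage order.
#' @export
downselect_montage <- function(eeg, montage) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(montage) == 0L) stop("montage is empty")
  targets <- names(montage)
  if (is.null(targets) || any(targets == "") || anyDuplicated(targets)) {
    stop("montage must be a named list with unique target labels")
  }
  out <- matrix(0, nrow = length(montage), ncol = ncol(eeg$data))
  for (i in seq_along(montage)) {
    src <- as.character(montage[[i]])
    missing <- setdiff(src, eeg$channel_names)
    if (length(missing) > 0L) {
      stop(sprintf(
        "unknown source channel(s) for target '%s': %s",
        targets[i], paste(missing, collapse = ", ")
      ))
    }
    out[i, ] <- colMeans(eeg$data[src, , drop = FALSE])
  }
  eeg_recording(out, eeg$fs, targets, eeg$t0)
}

# Linear-phase FIR band-pass, exact zero at DC, zero-phase application via
# group-delay compensation with edge reflection.
design_bandpass <- function(lo, hi, fs, n_taps) {
  h <- signal::fir1(n_taps - 1L, c(lo, hi) / (fs / 2), type = "pass")
  h <- as.numeric(h)
  h - mean(h) # force H(0) == 0 exactly
}

filt_zerophase <- function(x, h) {
  n <- length(x)
  p <- (length(h) - 1L) %/% 2L
  if (p < 1L) return(x * sum(h))
  left <- x[pmin(n, seq(p + 1L, 2L))]
  right <- x[pmax(1L, seq(n - 1L, n - p))]
  xp <- c(left, x, right)
  y <- signal::fftfilt(h, xp)
  y[seq(2L * p + 1L, length.out = n)]
}

#' Preprocess a raw EEG recording
#'
#' Re-references each channel to the average of the two mastoid leads,
#' down-samples to the target rate (anti-aliased, integer decimation), and
#' applies a zero-phase linear-phase FIR band-pass filter.
#'
#' @param eeg an `eeg_recording` at the raw sampling rate.
#' @param mastoid_labels labels of the two mastoid reference channels, or
#'   `NULL` to skip re-referencing (already-referenced data).
#' @param band numeric length-2, band-pass corner frequencies in Hz
#'   (default 0.5--50).
#' @param target_fs output sampling rate in Hz (default 256); must divide
#'   the input rate.
#' @return A preprocessed `eeg_recording` at `target_fs` (mastoid channels
#'   are retained as channels but referenced like the rest).
#' @export
preprocess_eeg <- function(eeg, mastoid_labels = NULL, band = c(0.5, 50),
                           target_fs = 256) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("`band` must be increasing positive corner frequencies")
  }
  if (band[2] >= target_fs / 2) {
    stop("band upper edge must be below the output Nyquist frequency")
  }
  x <- eeg$data
  if (!is.null(mastoid_labels)) {
    missing <- setdiff(mastoid_labels, eeg$channel_names)
    if (length(missing) > 0L) {
      stop(sprintf("mastoid channel(s) not found: %s", paste(missing, collapse = ", ")))
    }
    ref <- colMeans(x[mastoid_labels, , drop = FALSE])
    x <- sweep(x, 2L, ref, "-")
  }
  fs <- eeg$fs
  if (fs != target_fs) {
    q <- fs / target_fs
    if (abs(q - round(q)) > 1e-9) {
      stop("`target_fs` must divide the recording sampling rate")
    }
    q <- as.integer(round(q))
    # anti-alias below the new Nyquist before decimating
    n_aa <- min(511L, 2L * (ncol(x) %/% 3L) + 1L)
    if (n_aa >= 5L) {
      h_aa <- as.numeric(signal::fir1(n_aa - 1L, 0.9 / q, type = "low"))
      x <- t(apply(x, 1L, filt_zerophase, h = h_aa))
    }
    x <- x[, seq(1L, ncol(x), by = q), drop = FALSE]
    fs <- target_fs
  }
  # transition width ~3.3*fs/N; make it no wider than the low corner
  n_bp <- 2L * ceiling(3.3 * fs / min(band[1], 2) / 2) + 1L
  n_bp <- min(n_bp, 2L * (ncol(x) %/% 3L) + 1L)
  h <- design_bandpass(band[1], band[2], fs, n_bp)
  x <- t(apply(x, 1L, filt_zerophase, h = h))
  if (anyNA(x)) stop("preprocessing produced NaN values")
  eeg_recording(x, fs, eeg$channel_names, eeg$t0)
}
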