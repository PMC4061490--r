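# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (two-loop, textbook-formula) re-derivations
# and never call the code paths they check.

# -- naive sliding-epoch log-PSD (two nested loops, stats::fft/median) -------
naive_psd <- function(x, fs, epoch_len = 750, epoch_step = 500,
                      win_len = 125, win_step = 25, nfft = 256,
                      median_order = 5, freq_range = c(1, 40)) {
  n <- length(x)
  n_epoch <- (n - epoch_len) %/% epoch_step + 1
  nwin <- (epoch_len - win_len) %/% win_step + 1
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win_len - 1)) / (win_len - 1))
  bin_freq <- (0:(nfft %/% 2)) * fs / nfft
  keep <- which(bin_freq >= freq_range[1] - 1e-9 & bin_freq <= freq_range[2] + 1e-9)
  r_max <- (median_order - 1) %/% 2
  out <- matrix(0, n_epoch, length(keep))
  for (e in seq_len(n_epoch)) {
    e0 <- (e - 1) * epoch_step
    P <- matrix(0, length(keep), nwin)
    for (w in seq_len(nwin)) {
      seg <- x[e0 + (w - 1) * win_step + seq_len(win_len)] * hann
      sp <- fft(c(seg, rep(0, nfft - win_len)))
      P[, w] <- Mod(sp[keep])^2
    }
    Pf <- P
    for (j in seq_len(nwin)) {
      r <- min(r_max, j - 1, nwin - j)
      idx <- (j - r):(j + r)
      for (f in seq_len(nrow(P))) Pf[f, j] <- stats::median(P[f, idx])
    }
    out[e, ] <- log10(pmax(rowMeans(Pf), .Machine$double.xmin))
  }
  list(logpower = out, freqs = bin_freq[keep])
}

# -- brute-force centered windowed mean with first/last-valid padding --------
brute_smooth <- function(values, times, window, bstart = min(times),
                         bend = max(times)) {
  half <- window / 2
  sm <- vapply(times, function(t0) {
    mean(values[times >= t0 - half - 1e-9 & times <= t0 + half + 1e-9])
  }, 0)
  valid <- times >= bstart + half - 1e-9 & times <= bend - half + 1e-9
  if (any(valid)) {
    iv <- which(valid)
    sm[seq_len(min(iv) - 1)] <- sm[min(iv)]
    if (max(iv) < length(sm)) sm[(max(iv) + 1):length(sm)] <- sm[max(iv)]
  }
  sm
}

# -- textbook Benjamini-Hochberg step-up reject mask -------------------------
bh_stepup <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= (seq_len(m) / m) * alpha)
  reject <- rep(FALSE, m)
  if (length(k) > 0) reject[ord[seq_len(max(k))]] <- TRUE
  reject
}

# -- textbook Pearson correlation --------------------------------------------
pearson_oracle <- function(y, z) {
  ym <- y - mean(y)
  zm <- z - mean(z)
  sum(ym * zm) / sqrt(sum(ym^2) * sum(zm^2))
}

# -- assemble a psd_timeseries directly from an epochs x ch x freq array -----
tiny_psd <- function(arr, channel_names, blocks = NULL, dt = 2,
                     freqs = NULL) {
  n <- dim(arr)[1]
  if (is.null(freqs)) freqs <- seq_len(dim(arr)[3])
  if (is.null(blocks)) blocks <- rep(1L, n)
  tt <- numeric(n)
  for (b in unique(blocks)) {
    sel <- which(blocks == b)
    tt[sel] <- (b - 1) * 1e4 + dt * seq_along(sel)
  }
  psd_timeseries(arr, freqs, tt, channel_names, blocks)
}

# Random smooth latent-like series on an epoch grid (one value per epoch),
# smoothed so that the regression problem resembles the real pipeline.
smooth_noise <- function(n, span = 15) {
  as.numeric(stats::filter(rnorm(n + 2 * span), rep(1 / (2 * span + 1), 2 * span + 1),
                           sides = 2))[span + seq_len(n)]
}

# Planted-coupling feature set: `n_ch` channels x `n_freq` bins over blocks;
# informative channels add gain * latent to a band of bins; y is the latent
# plus noise.  Returns list(psd, y, informative).
planted_session <- function(n_ch = 5, n_freq = 40, n_blocks = 3,
                            epochs_per_block = 60, informative = c(1, 2),
                            gain = 1, noise = 0.05, y_noise = 0.05,
                            band = 8:12) {
  n <- n_blocks * epochs_per_block
  blocks <- rep(seq_len(n_blocks), each = epochs_per_block)
  latent <- smooth_noise(n)
  latent <- (latent - mean(latent)) / sd(latent)
  arr <- array(rnorm(n * n_ch * n_freq, sd = noise), dim = c(n, n_ch, n_freq))
  base <- matrix(rep(sin(seq_len(n_freq) / 3), each = n), n, n_freq)
  for (c in seq_len(n_ch)) arr[, c, ] <- arr[, c, ] + base
  for (c in informative) {
    arr[, c, band] <- arr[, c, band] + gain * latent
  }
  y <- latent + rnorm(n, sd = y_noise)
  list(psd = tiny_psd(arr, paste0("ch", seq_len(n_ch)), blocks),
       y = y, informative = paste0("ch", informative), blocks = blocks)
}

# All nonempty subsets of a character vector
all_subsets <- function(x) {
  out <- list()
  for (m in seq_along(x)) {
    cm <- utils::combn(x, m, simplify = FALSE)
    out <- c(out, cm)
  }
  out
}
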