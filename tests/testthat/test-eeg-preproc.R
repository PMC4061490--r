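test_that("montage down-selection averages source channels in map order", {
  x <- matrix(c(1, 1, 1, 3, 3, 3, 7, 7, 7), nrow = 3, byrow = TRUE)
  eeg <- eeg_recording(x, 256, c("Cz", "a", "b"))
  # singleton map returns the channel unchanged
  out <- downselect_montage(eeg, list(Cz = "Cz"))
  expect_equal(out$data[1, ], x[1, ])
  # mean of two constant channels
  out2 <- downselect_montage(eeg, list(Fz = c("a", "b")))
  expect_equal(unname(out2$data[1, ]), rep(5, 3))
  # output order and labels follow the map
  out3 <- downselect_montage(eeg, list(X = "b", Y = c("Cz", "a")))
  expect_equal(out3$channel_names, c("X", "Y"))
  expect_equal(unname(out3$data[2, ]), rep(2, 3))
  expect_error(downselect_montage(eeg, list(Z = "nope")), "nope")
})

test_that("larger montage maps give one output channel per entry", {
  set.seed(1)
  eeg <- eeg_recording(matrix(rnorm(64 * 100), 64), 256, sprintf("E%02d", 1:64))
  map <- lapply(seq_len(8), function(i) sprintf("E%02d", (i - 1) * 8 + 1:8))
  names(map) <- paste0("M", 1:8)
  out <- downselect_montage(eeg, map)
  expect_equal(nrow(out$data), 8L)
  expect_equal(out$channel_names, names(map))
  expect_equal(out$data[3, ], colMeans(eeg$data[map[[3]], ]), ignore_attr = TRUE)
})

test_that("preprocessing removes DC, attenuates 60 Hz, and decimates", {
  n <- 2560
  t <- (0:(n - 1)) / 256
  dc <- eeg_recording(matrix(5, 1, n), 256, "A")
  out <- preprocess_eeg(dc, band = c(0.5, 50), target_fs = 256)
  expect_lt(max(abs(out$data)), 1e-10)

  s60 <- eeg_recording(matrix(sin(2 * pi * 60 * t), 1, n), 256, "A")
  o60 <- preprocess_eeg(s60, band = c(0.5, 50), target_fs = 256)
  expect_lt(max(abs(o60$data[1, 500:2000])), 0.01) # < 1% of input amplitude

  s10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1, n), 256, "A")
  o10 <- preprocess_eeg(s10, band = c(0.5, 50), target_fs = 256)
  expect_equal(max(abs(o10$data[1, 500:2000])), 1, tolerance = 0.01)

  raw <- eeg_recording(matrix(rnorm(2 * 1024), 2, 1024), 1024, c("A", "M1"))
  o <- preprocess_eeg(raw, mastoid_labels = "M1", target_fs = 256)
  expect_equal(ncol(o$data), 256L)
  expect_equal(o$fs, 256)

  expect_error(preprocess_eeg(raw, mastoid_labels = c("M1", "M9")), "M9")
  expect_error(preprocess_eeg(raw, band = c(0.5, 200), target_fs = 256),
               "Nyquist")
})

test_that("mastoid referencing subtracts the mastoid mean from every channel", {
  x <- rbind(rnorm(512), rnorm(512) + 2, rnorm(512) - 2)
  eeg <- eeg_recording(x, 256, c("A", "M1", "M2"))
  ref <- colMeans(x[2:3, ])
  out <- preprocess_eeg(eeg, mastoid_labels = c("M1", "M2"),
                        band = c(0.5, 50), target_fs = 256)
  # compare against filtering the referenced signal directly
  direct <- preprocess_eeg(eeg_recording(sweep(x, 2, ref), 256, c("A", "M1", "M2")),
                           band = c(0.5, 50), target_fs = 256)
  expect_equal(out$data, direct$data, tolerance = 1e-12)
})

test_that("PSD epoch/window arithmetic and peak location are correct", {
  fs <- 256
  for (n in c(750, 1250, 2049, 4000)) {
    x <- eeg_recording(matrix(rnorm(n), 1), fs, "A")
    p <- compute_psd(x)
    expect_equal(dim(p$logpower)[1], (n - 750) %/% 500 + 1)
  }
  # 26 windows per epoch under the defaults
  expect_equal((750 - 125) %/% 25 + 1, 26)

  t <- (0:(3000 - 1)) / fs
  s10 <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "A")
  p <- compute_psd(s10)
  peaks <- apply(p$logpower[, 1, ], 1, which.max)
  expect_true(all(p$freqs[peaks] == 10))

  expect_error(compute_psd(eeg_recording(matrix(rnorm(700), 1), fs, "A")),
               "shorter")
  expect_error(compute_psd(s10, median_order = 4), "odd")
})

test_that("compute_psd equals the naive two-loop reference", {
  set.seed(7)
  fs <- 256
  x <- rnorm(10 * fs)
  eeg <- eeg_recording(rbind(x, 3 * x + rnorm(length(x))), fs, c("A", "B"))
  p <- compute_psd(eeg)
  for (ch in 1:2) {
    ref <- naive_psd(eeg$data[ch, ], fs)
    expect_equal(p$logpower[, ch, ], ref$logpower, tolerance = 1e-9)
    expect_equal(p$freqs, ref$freqs)
  }
  expect_equal(p$freqs, 1:40)
})

test_that("the across-window median filter suppresses a brief artifact burst", {
  # A 50 ms burst overlaps ~6 of the 26 sliding segments (125-pt windows,
  # 25-pt steps), so a 5th-order median cannot reject it completely; the
  # check is that it strictly reduces the distortion relative to the
  # median-free oracle, strongly so for moderate bursts.
  fs <- 256
  t <- (0:(999)) / fs
  clean <- sin(2 * pi * 10 * t)
  p_clean <- compute_psd(eeg_recording(matrix(clean, 1), fs, "A"))
  for (amp in c(100, 10)) {
    burst <- clean
    k <- 400 + seq_len(13) # ~50 ms
    burst[k] <- burst[k] * amp
    p_burst <- compute_psd(eeg_recording(matrix(burst, 1), fs, "A"))
    p_nomed <- compute_psd(eeg_recording(matrix(burst, 1), fs, "A"),
                           median_order = 1)
    d_med <- max(abs(p_burst$logpower[, 1, 10] - p_clean$logpower[, 1, 10]))
    d_nomed <- max(abs(p_nomed$logpower[, 1, 10] - p_clean$logpower[, 1, 10]))
    expect_lt(d_med, 0.8 * d_nomed)
  }
  # a mild (3x) burst stays within 0.5 dB of the clean spectrum
  burst3 <- clean
  burst3[400 + seq_len(13)] <- burst3[400 + seq_len(13)] * 3
  p3 <- compute_psd(eeg_recording(matrix(burst3, 1), fs, "A"))
  expect_lt(max(10 * abs(p3$logpower[, 1, 10] - p_clean$logpower[, 1, 10])),
            0.5)
})

test_that("log transform is monotone in channel scale", {
  set.seed(8)
  x <- rnorm(1000)
  p1 <- compute_psd(eeg_recording(matrix(x, 1), 256, "A"))
  p2 <- compute_psd(eeg_recording(matrix(3 * x, 1), 256, "A"))
  expect_true(all(p2$logpower > p1$logpower))
})

test_that("smoothing: constant, ramp and impulse match brute force", {
  tt <- 0:90
  expect_equal(smooth_series(rep(4, 91), tt, window = 90), rep(4, 91))
  # linear ramp: interior points unchanged by a centered symmetric mean
  ramp <- 0.5 * tt
  sm <- smooth_series(ramp, tt, window = 30)
  interior <- tt >= 15 & tt <= 75
  expect_equal(sm[interior], ramp[interior])
  # unit impulse at the center of a 91 s series: plateau of 1/91
  imp <- rep(0, 91)
  imp[46] <- 1
  sm_imp <- smooth_series(imp, tt, window = 90)
  expect_equal(sm_imp, rep(1 / 91, 91))
  expect_equal(sm_imp, brute_smooth(imp, tt, 90))
  # brute-force agreement on irregular grids
  set.seed(3)
  t_irr <- sort(runif(80, 0, 200))
  v <- rnorm(80)
  expect_equal(smooth_series(v, t_irr, window = 60),
               brute_smooth(v, t_irr, 60))
  expect_error(smooth_series(numeric(0), numeric(0)), "empty")
})

test_that("smoothing commutes with constants, ignores time origin, respects blocks", {
  set.seed(4)
  tt <- seq(0, 300, by = 2)
  v <- rnorm(length(tt))
  s1 <- smooth_series(v, tt, window = 90)
  expect_equal(smooth_series(v + 7, tt, window = 90), s1 + 7)
  expect_equal(smooth_series(v, tt + 1234, window = 90), s1)
  # two blocks smoothed independently == concatenation of per-block smooths
  blk <- rep(1:2, each = length(tt))
  v2 <- c(v, rev(v))
  t2 <- c(tt, 1000 + tt)
  s2 <- smooth_series(v2, t2, window = 90, block_id = blk)
  expect_equal(s2[blk == 1], s1)
  expect_equal(s2[blk == 2], smooth_series(rev(v), tt, window = 90))
})

test_that("blocks shorter than the window fall back to clipped-window means", {
  tt <- seq(0, 40, by = 2) # 40 s block, 90 s window: no valid point
  v <- rnorm(length(tt))
  sm <- smooth_series(v, tt, window = 90)
  expect_equal(sm, rep(mean(v), length(v))) # every window covers the block
})
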