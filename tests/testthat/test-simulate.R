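small_cfg <- function(...) {
  sim_config(n_blocks = 2, block_len = 120,
             channel_names = c("Fz", "Cz", "Pz", "Oz"), ...)
}

test_that("simulators are pure functions of (config, seed)", {
  cfg <- small_cfg()
  s1 <- simulate_session(cfg, seed = 3, task = "both")
  s2 <- simulate_session(cfg, seed = 3, task = "both")
  expect_identical(s1$latent, s2$latent)
  expect_identical(s1$eeg$data, s2$eeg$data)
  expect_identical(s1$vehicle_log, s2$vehicle_log)
  expect_identical(s1$rsvp$events, s2$rsvp$events)
  expect_identical(s1$rsvp$presses, s2$rsvp$presses)
  s3 <- simulate_session(cfg, seed = 4, task = "both")
  expect_false(identical(s1$eeg$data, s3$eeg$data))
})

test_that("zero latent scale freezes the latent state", {
  cfg <- small_cfg(latent_sd = 0, latent_drift = 0)
  l <- simulate_latent(cfg, seed = 1)
  expect_equal(l$values, rep(0, length(l$values)))
})

test_that("the latent state has the configured mean-reverting autocorrelation", {
  # a single session gives a noisy autocorrelation estimate (few
  # independent stretches of length tau); average over seeds
  cfg <- sim_config(n_blocks = 6, block_len = 600, latent_drift = 0,
                    channel_names = c("Fz", "Cz"))
  for (lag in c(10, 30, 60)) {
    emp <- mean(vapply(1:12, function(sd0) {
      l <- simulate_latent(cfg, seed = sd0)
      n <- length(l$values)
      cor(l$values[1:(n - lag)], l$values[(lag + 1):n])
    }, 0))
    # absolute band: the sample ACF is biased low by ~2*tau/T per session
    expect_lt(abs(emp - exp(-lag / cfg$latent_tau)), 0.12)
  }
})

test_that("coupled channels' band log power tracks the latent state", {
  cfg <- sim_config(n_blocks = 2, block_len = 300,
                    channel_names = c("Fz", "Cz", "Pz", "Oz"))
  s <- simulate_session(cfg, seed = 6, task = "driving")
  psd <- compute_psd_blocks(s$eeg, s$blocks)
  psd <- smooth_psd(psd, 90, s$blocks)
  lat <- approx(s$latent$times, s$latent$values, xout = psd$epoch_times,
                rule = 2)$y
  alpha_oz <- rowMeans(psd$logpower[, 4, 8:12])
  theta_fz <- rowMeans(psd$logpower[, 1, 4:7])
  expect_gt(cor(lat, alpha_oz), 0.5) # positive alpha coupling
  expect_lt(cor(lat, theta_fz), -0.5) # negative theta coupling
  expect_false(anyNA(psd$logpower)) # survives the PSD pipeline
})

test_that("zero-gain channels have stationary block-wise band power", {
  cfg <- sim_config(n_blocks = 4, block_len = 150,
                    channel_names = c("Fz", "Cz"),
                    coupling = data.frame(channel = character(0),
                                          band = character(0),
                                          gain = numeric(0)))
  s <- simulate_session(cfg, seed = 8, task = "driving")
  psd <- compute_psd_blocks(s$eeg, s$blocks)
  a <- rowMeans(psd$logpower[, 1, 8:12])
  bm <- tapply(a, psd$epoch_blocks, mean)
  se <- sd(a) / sqrt(length(a) / 4)
  expect_lt(max(bm) - min(bm), 6 * se)
})

test_that("driving wander grows with the latent state", {
  cfg <- small_cfg()
  lat <- simulate_latent(cfg, seed = 9)
  # force a low and a high half by overwriting the latent trajectory
  lat$values <- rep(c(-1.5, 1.5), each = length(lat$values) / 2)
  log <- simulate_driving(cfg, lat, seed = 10)
  half <- nrow(log) / 2
  expect_gt(mean(abs(log$lane_offset[(half + 1):nrow(log)])),
            mean(abs(log$lane_offset[1:half])))
  expect_equal(nrow(log), cfg$n_blocks * cfg$block_len * cfg$v_fs)
})

test_that("RSVP stream respects rate, blink cadence and block probabilities", {
  cfg <- sim_config(n_blocks = 6, block_len = 120,
                    channel_names = c("Fz", "Cz"))
  lat <- simulate_latent(cfg, seed = 11)
  r <- simulate_rsvp(cfg, lat, seed = 12)
  ev <- r$events
  expect_equal(nrow(ev), 6 * 120 * 5)
  # inter-onset interval 200 ms within blocks
  expect_equal(unique(round(diff(ev$t_onset_s[ev$block_id == 1]), 6)), 0.2)
  expect_equal(sum(ev$is_blink), 6 * 12) # every 10 s
  expect_false(any(ev$is_blink & ev$is_target))
  # per-block target counts close to probability * image count (binomial)
  for (b in unique(ev$block_id)) {
    e <- ev[ev$block_id == b & !ev$is_blink, ]
    p <- e$target_prob[1]
    n <- nrow(e)
    expect_lt(abs(sum(e$is_target) - p * n), 4 * sqrt(n * p * (1 - p)) + 1)
  }
  # last block repeats the first block's target class
  expect_equal(r$block_info$target_class[6], r$block_info$target_class[1])
  expect_equal(sort(r$block_info$target_prob),
               c(0.01, 0.03, 0.05, 0.07, 0.09, 0.11))
})

test_that("hit rates follow the configured psychometric model", {
  # no latent or difficulty effect: overall hit rate ~ logistic intercept
  cfg <- sim_config(n_blocks = 6, block_len = 200,
                    channel_names = c("Fz", "Cz"),
                    rsvp = list(acc_latent = 0, acc_difficulty = 0,
                                fa_rate_per_min = 0))
  lat <- simulate_latent(cfg, seed = 13)
  r <- simulate_rsvp(cfg, lat, seed = 14)
  p_hat <- mean(r$truth$hit)
  n <- nrow(r$truth)
  p_exp <- plogis(cfg$rsvp$acc_intercept)
  expect_lt(abs(p_hat - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / n))
  # easy images at high alertness: near-ceiling accuracy
  cfg2 <- sim_config(n_blocks = 2, block_len = 200, latent_sd = 0,
                     channel_names = c("Fz", "Cz"),
                     rsvp = list(class_effects = rep(-2, 5),
                                 fa_rate_per_min = 0))
  lat2 <- simulate_latent(cfg2, seed = 15)
  r2 <- simulate_rsvp(cfg2, lat2, seed = 16)
  expect_gt(mean(r2$truth$hit), 0.95)
})

test_that("ground truth reports the informative channel set", {
  s <- simulate_session(small_cfg(), seed = 17, task = "driving")
  expect_setequal(s$ground_truth$informative_channels,
                  c("Fz", "Cz", "Pz", "Oz"))
  cfg0 <- small_cfg(coupling = data.frame(channel = "Pz", band = "alpha",
                                          gain = 0.4))
  s0 <- simulate_session(cfg0, seed = 18, task = "driving")
  expect_equal(s0$ground_truth$informative_channels, "Pz")
})
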