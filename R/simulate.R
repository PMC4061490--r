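# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic session generator.  The defaults emulate a
#' six-block, ten-minutes-per-block session recorded from a 32-channel
#' montage at 256 Hz, with a slow latent alertness state (an
#' Ornstein--Uhlenbeck process, time constant 120 s, plus a mild
#' within-block drift) that modulates EEG band power on four informative
#' midline channels (theta down, alpha up as alertness falls) and drives
#' lane-keeping error, RSVP detection accuracy, reaction time and
#' button-press duration.
#'
#' @param n_blocks number of blocks (default 6).
#' @param block_len block length in seconds (default 600).
#' @param fs EEG sampling rate in Hz (default 256).
#' @param channel_names EEG montage (default [biosemi32_channels()]).
#' @param latent_tau latent-state time constant in seconds (default 120).
#' @param latent_sd overall scale of the standardized latent fluctuation
#'   (default 1; 0 freezes the state, removing every latent-driven effect).
#' @param latent_drift amplitude of the within-block upward drift, in
#'   latent-SD units (default 0.3; mimics within-block performance
#'   decrements).
#' @param coupling data.frame (`channel`, `band`, `gain`): which channels'
#'   band power is modulated by the latent state and how strongly.  A
#'   positive gain raises band power when the latent state (drowsiness)
#'   rises.
#' @param bands named list of band edges in Hz.
#' @param bg_sd broadband background noise SD in microvolts (default 15).
#' @param osc_amp named baseline oscillation amplitudes in microvolts for
#'   bands present on every channel (default theta 7, alpha 9).
#' @param mod_floor lower clip of the amplitude modulation factor.
#' @param v_fs vehicle-log sampling rate (default 100 Hz).
#' @param lane_tau,lane_sd,lane_gain lane-wander AR time constant (s),
#'   stationary SD (m) and latent modulation of the innovation scale.
#' @param rsvp list of RSVP parameters (presentation rate, blink period,
#'   block target probabilities, target classes and their mean perceptual
#'   difficulty, response-model coefficients).  The probability effects on
#'   RT and press duration use slopes of -262 and -277 ms per unit
#'   probability so that the block-wise probability adjustment removes
#'   them exactly in expectation.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 6L, block_len = 600, fs = 256,
                       channel_names = biosemi32_channels(),
                       latent_tau = 120, latent_sd = 1, latent_drift = 0.3,
                       coupling = NULL,
                       bands = list(theta = c(4, 7), alpha = c(8, 12),
                                    beta = c(13, 30)),
                       bg_sd = 15,
                       osc_amp = c(theta = 7, alpha = 9, beta = 0),
                       mod_floor = 0.15,
                       v_fs = 100, lane_tau = 2, lane_sd = 0.3,
                       lane_gain = 0.45,
                       rsvp = list()) {
  if (is.null(coupling)) {
    coupling <- data.frame(
      channel = c("Fz", "Cz", "Pz", "Oz"),
      band = c("theta", "theta", "alpha", "alpha"),
      gain = c(-0.35, -0.35, 0.35, 0.35),
      stringsAsFactors = FALSE
    )
  }
  coupling <- coupling[coupling$channel %in% channel_names, , drop = FALSE]
  rsvp_defaults <- list(
    rate = 5, blink_period = 10,
    target_probs = c(0.01, 0.03, 0.05, 0.07, 0.09, 0.11),
    classes = c("stair", "container", "poster", "chair", "door"),
    class_effects = c(-1, -0.5, 0, 0.5, 1),
    n_images_per_class = 150L, difficulty_sd = 0.5, n_nontarget = 2000L,
    acc_intercept = 2.2, acc_latent = 0.9, acc_difficulty = 1.1,
    rt_base = 600, rt_latent = 70, rt_difficulty = 60, rt_sd = 80,
    rt_prob_slope = -262, rt_clip = c(300, 1000),
    dur_base = 300, dur_latent = 45, dur_sd = 40, dur_prob_slope = -277,
    dur_clip = c(50, 1500),
    fa_rate_per_min = 1, fa_latent = 0.3, prob_ref = 0.06
  )
  rsvp <- utils::modifyList(rsvp_defaults, rsvp)
  stopifnot(n_blocks >= 1, block_len > 0, fs > 0,
            all(rsvp$target_probs > 0 & rsvp$target_probs < 1))
  structure(
    list(n_blocks = as.integer(n_blocks), block_len = block_len, fs = fs,
         channel_names = channel_names, latent_tau = latent_tau,
         latent_sd = latent_sd,
         latent_drift = latent_drift, coupling = coupling, bands = bands,
         bg_sd = bg_sd, osc_amp = osc_amp, mod_floor = mod_floor,
         v_fs = v_fs, lane_tau = lane_tau, lane_sd = lane_sd,
         lane_gain = lane_gain, rsvp = rsvp),
    class = "sim_config"
  )
}

#' Block boundary table of a simulated session
#' @param config a `sim_config`.
#' @return data.frame: `block`, `start`, `end` (seconds, half-open).
#' @export
sim_blocks <- function(config) {
  b <- seq_len(config$n_blocks)
  data.frame(block = b, start = (b - 1) * config$block_len,
             end = b * config$block_len)
}

#' Simulate the latent alertness state
#'
#' An Ornstein--Uhlenbeck path sampled at 1 Hz (mean-reverting with time
#' constant `latent_tau`), plus an optional within-block upward drift, and
#' standardized over the session.  High values represent low alertness.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return list: `times` (s), `values` (zero mean, unit SD).
#' @export
simulate_latent <- function(config, seed) {
  with_seed(seed, {
    T_s <- config$n_blocks * config$block_len
    tt <- seq(0, T_s - 1)
    a <- exp(-1 / config$latent_tau)
    innov <- rnorm(length(tt), sd = sqrt(1 - a^2))
    innov[1] <- rnorm(1) # stationary start
    l <- as.numeric(stats::filter(innov, a, method = "recursive"))
    t_in_block <- tt %% config$block_len
    l <- l + config$latent_drift * (t_in_block / config$block_len - 0.5) * 2
    if (sd(l) > 0) l <- (l - mean(l)) / sd(l)
    l <- l * config$latent_sd # overall fluctuation scale; 0 freezes the state
    list(times = tt, values = l)
  })
}

# latent value at arbitrary times (linear interpolation, clamped ends)
latent_at <- function(latent, t) {
  approx(latent$times, latent$values, xout = t, rule = 2)$y
}

# unit-variance narrowband oscillation via phase diffusion; the phase
# random walk only has spectral content up to ~bw Hz, so it is sampled on
# a coarse grid and linearly interpolated to the sample grid
narrowband_unit <- function(n, fc, bw, fs) {
  dec <- max(1L, floor(fs / (16 * bw)))
  n_c <- ceiling(n / dec) + 1L
  sigma_phi <- sqrt(2 * pi * bw / fs)
  walk <- cumsum(rnorm(n_c, sd = sigma_phi * sqrt(dec)))
  drift <- if (dec > 1L) {
    # regular-grid linear interpolation, vectorized
    i0 <- rep(seq_len(n_c - 1L), each = dec)[seq_len(n)]
    fr <- rep((0:(dec - 1L)) / dec, length.out = n)
    walk[i0] * (1 - fr) + walk[i0 + 1L] * fr
  } else {
    walk[seq_len(n)]
  }
  phase <- 2 * pi * fc * (0:(n - 1)) / fs + drift
  sqrt(2) * cos(phase)
}

#' Simulate a multichannel EEG session
#'
#' Each channel is a smooth broadband background (a mixture of low-pass
#' autoregressive noise and white noise, emphasizing low frequencies) plus
#' band-limited theta and alpha oscillations.  On informative channels the
#' instantaneous oscillation amplitude is modulated by
#' `1 + gain * latent` (clipped below), so band log-power tracks the
#' latent state; uninformative channels carry the same oscillations at
#' constant amplitude.
#'
#' @param config a `sim_config`.
#' @param latent output of [simulate_latent()].
#' @param seed RNG seed.
#' @return An `eeg_recording` spanning the session (blocks contiguous).
#' @export
simulate_eeg <- function(config, latent, seed) {
  with_seed(seed, {
    fs <- config$fs
    n_blk <- round(config$block_len * fs)
    n_ch <- length(config$channel_names)
    blocks <- sim_blocks(config)
    data <- matrix(0, nrow = n_ch, ncol = n_blk * config$n_blocks,
                   dimnames = list(config$channel_names, NULL))
    for (bi in seq_len(config$n_blocks)) {
      t_samp <- blocks$start[bi] + (0:(n_blk - 1)) / fs
      l_samp <- latent_at(latent, t_samp)
      col0 <- (bi - 1L) * n_blk
      blk_data <- matrix(0, nrow = n_blk, ncol = n_ch) # column-major writes
      for (ci in seq_len(n_ch)) {
        ch <- config$channel_names[ci]
        # broadband background: low-pass AR noise plus white noise, scaled
        # by the theoretical (stationary) mixture SD
        w <- rnorm(2L * n_blk)
        bg1 <- as.numeric(stats::filter(w[seq_len(n_blk)], 0.985,
                                        method = "recursive"))
        a_sd <- 1 / sqrt(1 - 0.985^2)
        bg <- 0.9 * bg1 / a_sd + 0.45 * w[n_blk + seq_len(n_blk)]
        x <- config$bg_sd * bg / sqrt(0.9^2 + 0.45^2)
        for (band in names(config$bands)) {
          amp <- if (band %in% names(config$osc_amp)) config$osc_amp[[band]] else 0
          cp <- config$coupling
          g <- cp$gain[cp$channel == ch & cp$band == band]
          g <- if (length(g) > 0) g[1] else 0
          if (amp <= 0 && g != 0) amp <- 8 # coupled band needs carrier power
          if (amp <= 0) next
          edges <- config$bands[[band]]
          osc <- narrowband_unit(n_blk, mean(edges), diff(edges) / 2, fs)
          if (g != 0) {
            osc <- osc * pmax(config$mod_floor, 1 + g * l_samp)
          }
          x <- x + amp * osc
        }
        blk_data[, ci] <- x
      }
      data[, col0 + seq_len(n_blk)] <- t(blk_data)
    }
    eeg_recording(data, fs, config$channel_names, t0 = 0)
  })
}

#' Simulate the driving task vehicle log
#'
#' Lane offset follows a fast mean-reverting wander whose innovation scale
#' grows with the latent state, so the smoothed absolute lane deviation
#' rises when alertness falls.
#'
#' @param config a `sim_config`.
#' @param latent output of [simulate_latent()].
#' @param seed RNG seed.
#' @return data.frame: `t`, `lane_offset` (m), `block_id` at `v_fs` Hz.
#' @export
simulate_driving <- function(config, latent, seed) {
  with_seed(seed, {
    fs <- config$v_fs
    n_blk <- round(config$block_len * fs)
    rho <- exp(-1 / (fs * config$lane_tau))
    sd_innov <- config$lane_sd * sqrt(1 - rho^2)
    blocks <- sim_blocks(config)
    out <- vector("list", config$n_blocks)
    for (bi in seq_len(config$n_blocks)) {
      t_samp <- blocks$start[bi] + (0:(n_blk - 1)) / fs
      l_samp <- latent_at(latent, t_samp)
      scale <- pmax(0.2, 1 + config$lane_gain * l_samp)
      x <- as.numeric(stats::filter(sd_innov * scale * rnorm(n_blk), rho,
                                    method = "recursive"))
      out[[bi]] <- data.frame(t = t_samp, lane_offset = x, block_id = bi)
    }
    do.call(rbind, out)
  })
}

#' Target and non-target image library
#'
#' Fixed pool of images shared across simulated participants.  Each target
#' image carries a perceptual difficulty (class mean effect plus
#' image-level scatter) that is identical for every participant, which is
#' exactly the structure the per-image grand-average normalization is
#' designed to remove.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (use the same seed across participants!).
#' @return data.frame: `image_id`, `class` (NA for non-targets),
#'   `difficulty`, `is_target_pool`.
#' @export
image_library <- function(config, seed) {
  with_seed(seed, {
    p <- config$rsvp
    tgt <- do.call(rbind, lapply(seq_along(p$classes), function(i) {
      data.frame(
        image_id = sprintf("T_%s_%03d", p$classes[i], seq_len(p$n_images_per_class)),
        class = p$classes[i],
        difficulty = p$class_effects[i] + rnorm(p$n_images_per_class,
                                                sd = p$difficulty_sd),
        is_target_pool = TRUE, stringsAsFactors = FALSE
      )
    }))
    nt <- data.frame(
      image_id = sprintf("NT_%05d", seq_len(p$n_nontarget)),
      class = NA_character_, difficulty = 0, is_target_pool = FALSE,
      stringsAsFactors = FALSE
    )
    rbind(tgt, nt)
  })
}

#' Simulate the RSVP task: image stream, responses and button presses
#'
#' Images at 5 Hz with a blink screen every 10 s; per-block target class
#' and target probability; per-trial hit probability, RT and press
#' duration driven by the latent state, the image's perceptual difficulty
#' and the block's target probability; occasional false alarms at a mildly
#' latent-dependent rate.
#'
#' @param config a `sim_config`.
#' @param latent output of [simulate_latent()].
#' @param seed RNG seed.
#' @param library image library from [image_library()] (shared across
#'   participants); generated from seed 9999 when omitted.
#' @return list: `events` (image stream), `presses`, `block_info`,
#'   `truth` (per-target generative values).
#' @export
simulate_rsvp <- function(config, latent, seed, library = NULL) {
  if (is.null(library)) library <- image_library(config, seed = 9999L)
  with_seed(seed, {
    p <- config$rsvp
    lib_t <- library[library$is_target_pool, , drop = FALSE]
    lib_nt <- library[!library$is_target_pool, , drop = FALSE]
    n_blocks <- config$n_blocks
    ord <- sample(p$classes, min(length(p$classes), n_blocks))
    ord <- rep(ord, length.out = n_blocks)
    if (n_blocks >= 2L) ord[n_blocks] <- ord[1] # last block repeats the first
    probs <- if (n_blocks <= length(p$target_probs)) {
      sample(p$target_probs, n_blocks)
    } else {
      sample(p$target_probs, n_blocks, replace = TRUE)
    }
    blocks <- sim_blocks(config)
    ev_list <- list()
    press_list <- list()
    truth_list <- list()
    for (bi in seq_len(n_blocks)) {
      n_slots <- round(config$block_len * p$rate)
      t_on <- blocks$start[bi] + (0:(n_slots - 1)) / p$rate
      is_blink <- ((0:(n_slots - 1)) %% round(p$blink_period * p$rate)) == 0L
      n_img <- sum(!is_blink)
      is_tgt <- rep(FALSE, n_slots)
      is_tgt[!is_blink] <- runif(n_img) < probs[bi]
      ids <- rep(NA_character_, n_slots)
      diff <- rep(0, n_slots)
      cls_pool <- lib_t[lib_t$class == ord[bi], , drop = FALSE]
      n_t <- sum(is_tgt)
      if (n_t > 0L) {
        pick <- sample.int(nrow(cls_pool), n_t, replace = TRUE)
        ids[is_tgt] <- cls_pool$image_id[pick]
        diff[is_tgt] <- cls_pool$difficulty[pick]
      }
      n_nt <- sum(!is_blink & !is_tgt)
      ids[!is_blink & !is_tgt] <- lib_nt$image_id[sample.int(nrow(lib_nt), n_nt,
                                                             replace = TRUE)]
      ev <- data.frame(
        t_onset_s = t_on, image_id = ids, is_target = is_tgt,
        is_blink = is_blink, block_id = bi, target_class = ord[bi],
        target_prob = probs[bi], stringsAsFactors = FALSE
      )
      ev_list[[bi]] <- ev

      # responses to targets
      if (n_t > 0L) {
        tt <- t_on[is_tgt]
        d <- diff[is_tgt]
        l <- latent_at(latent, tt)
        p_hit <- plogis(p$acc_intercept - p$acc_latent * l - p$acc_difficulty * d)
        hit <- rbinom(n_t, 1L, p_hit) == 1L
        rt <- p$rt_base + p$rt_latent * l + p$rt_difficulty * d +
          p$rt_prob_slope * (probs[bi] - p$prob_ref) + rnorm(n_t, sd = p$rt_sd)
        rt <- pmin(pmax(rt, p$rt_clip[1]), p$rt_clip[2])
        dur <- p$dur_base + p$dur_latent * l +
          p$dur_prob_slope * (probs[bi] - p$prob_ref) + rnorm(n_t, sd = p$dur_sd)
        dur <- pmin(pmax(dur, p$dur_clip[1]), p$dur_clip[2])
        truth_list[[bi]] <- data.frame(
          t_onset_s = tt, image_id = ids[is_tgt], block_id = bi,
          latent = l, difficulty = d, p_hit = p_hit, hit = hit,
          rt_ms = ifelse(hit, rt, NA_real_), stringsAsFactors = FALSE
        )
        if (any(hit)) {
          on <- tt[hit] + rt[hit] / 1000
          press_list[[length(press_list) + 1L]] <- data.frame(
            press_on_s = on, press_off_s = on + dur[hit] / 1000
          )
        }
      }
      # false alarms on non-target images
      nt_on <- t_on[!is_blink & !is_tgt]
      if (length(nt_on) > 0L && p$fa_rate_per_min > 0) {
        l_nt <- latent_at(latent, nt_on)
        w <- pmax(0, 1 + p$fa_latent * l_nt)
        lambda <- p$fa_rate_per_min * config$block_len / 60 * mean(w)
        n_fa <- rpois(1L, lambda)
        if (n_fa > 0L) {
          pick <- sample.int(length(nt_on), min(n_fa, length(nt_on)),
                             prob = w + 1e-12)
          on <- nt_on[pick] + 0.6 + rnorm(length(pick), sd = 0.1)
          dur <- pmax(50, p$dur_base + rnorm(length(pick), sd = p$dur_sd))
          press_list[[length(press_list) + 1L]] <- data.frame(
            press_on_s = on, press_off_s = on + dur / 1000
          )
        }
      }
    }
    presses <- do.call(rbind, press_list)
    if (is.null(presses)) {
      presses <- data.frame(press_on_s = numeric(0), press_off_s = numeric(0))
    }
    presses <- presses[order(presses$press_on_s), , drop = FALSE]
    rownames(presses) <- NULL
    list(
      events = do.call(rbind, ev_list),
      presses = presses,
      block_info = data.frame(block = seq_len(n_blocks), target_class = ord,
                              target_prob = probs),
      truth = do.call(rbind, truth_list)
    )
  })
}

#' Simulate a complete session
#'
#' Latent state, EEG, and the behavioral stream(s) of the requested task,
#' all driven by the same latent trajectory, plus the ground truth needed
#' by recovery tests.  Deterministic given `(config, seed)`.
#'
#' @param config a `sim_config`.
#' @param seed base RNG seed (sub-seeds are derived per component).
#' @param task `"driving"`, `"rsvp"` or `"both"`.
#' @param library optional shared image library for the RSVP task.
#' @return list: `config`, `seed`, `latent`, `eeg`, `blocks`,
#'   `vehicle_log` and/or `rsvp`, `ground_truth` (latent trajectory and
#'   the informative channel set).
#' @export
simulate_session <- function(config = sim_config(), seed = 1L,
                             task = c("driving", "rsvp", "both"),
                             library = NULL) {
  task <- match.arg(task)
  latent <- simulate_latent(config, seed = seed * 11L + 1L)
  eeg <- simulate_eeg(config, latent, seed = seed * 11L + 2L)
  blocks <- sim_blocks(config)
  out <- list(config = config, seed = seed, latent = latent, eeg = eeg,
              blocks = blocks)
  if (task %in% c("driving", "both")) {
    out$vehicle_log <- simulate_driving(config, latent, seed = seed * 11L + 3L)
  }
  if (task %in% c("rsvp", "both")) {
    out$rsvp <- simulate_rsvp(config, latent, seed = seed * 11L + 4L,
                              library = library)
  }
  inf <- config$coupling[config$coupling$gain != 0, , drop = FALSE]
  out$ground_truth <- list(latent = latent,
                           informative_channels = unique(inf$channel),
                           coupling = config$coupling)
  out
}
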