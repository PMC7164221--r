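DEFAULT_CHANNELS <- c("Cz", "C3", "C4", "CP3", "CP4", "FCz", "CPz", "Pz")

#' Configuration for the synthetic gait-session generator
#'
#' Describes an overground gait protocol of alternating rest and walk states:
#' the subject rests, starts walking in a self-paced manner, walks, stops,
#' and rests again, for `n_cycles` cycles. Rest and walk state durations are
#' drawn uniformly from `[min, min + 3]` seconds. Band-limited alpha and
#' beta power over sensorimotor channels is reduced (event-related
#' desynchronization, ERD) beginning `erd_lead_s` seconds before each gait
#' start and stop event: the oscillator amplitude ramps linearly down to
#' `sqrt(1 - drop)` of baseline over `erd_ramp_s` seconds, holds until
#' `erd_hold_s` after the event, and then releases over `erd_ramp_s`.
#'
#' @param n_cycles number of start->stop gait cycles (>= 1).
#' @param fs sampling rate in Hz.
#' @param channels ordered channel labels (default: the eight 10-20
#'   sensorimotor sites Cz, C3, C4, CP3, CP4, FCz, CPz, Pz).
#' @param min_walk_s,min_rest_s minimum state durations in seconds; the
#'   protocol being emulated requires at least 5 s of each.
#' @param erd_lead_s seconds before each event at which band power begins to
#'   drop (pre-movement desynchronization onset).
#' @param erd_ramp_s,erd_hold_s ERD envelope ramp and post-event hold (s).
#' @param alpha_drop,beta_drop fractional band power reduction in `[0, 1]`.
#' @param alpha_amp,beta_amp oscillator amplitudes (uV).
#' @param amp_mod relative SD of the slow (~0.2 Hz) random amplitude
#'   modulation of both oscillators, emulating the natural waxing and
#'   waning of ongoing band power; `0` gives constant-amplitude carriers.
#' @param noise_scale broadband 1/f background amplitude (uV SD).
#' @param walk_mod fractional ~1 Hz rhythmic modulation of the broadband
#'   background during walking, so walk and rest states are not identical.
#' @param artifacts an [artifact_spec()].
#' @param subject subject tag recorded in session metadata.
#' @param seed integer randomness seed; identical configs give bit-identical
#'   sessions.
#' @return An object of class `gi_synth_config`.
#' @export
synth_config <- function(n_cycles = 10, fs = 500, channels = DEFAULT_CHANNELS,
                         min_walk_s = 5, min_rest_s = 5,
                         erd_lead_s = 1.5, erd_ramp_s = 0.5, erd_hold_s = 0.5,
                         alpha_drop = 0.5, beta_drop = 0.5,
                         alpha_amp = 4, beta_amp = 2, amp_mod = 0.3,
                         noise_scale = 2, walk_mod = 0.1,
                         artifacts = artifact_spec(),
                         subject = "synthetic", seed = 1L) {
  assert_that(is_number(n_cycles) && n_cycles >= 1, "n_cycles must be >= 1")
  assert_that(is_number(fs) && fs > 0, "fs must be positive")
  assert_that(length(channels) >= 1, "channel list must be non-empty")
  assert_that(!anyDuplicated(channels), "channel labels must be unique")
  for (d in c(alpha_drop, beta_drop))
    assert_that(is_number(d) && d >= 0 && d <= 1,
                "band power drops must lie in [0, 1]")
  assert_that(min_walk_s > 0 && min_rest_s > 0, "state minima must be positive")
  assert_that(erd_lead_s >= 0 && erd_ramp_s > 0, "invalid ERD timing")
  stopifnot(inherits(artifacts, "gi_artifact_spec"))
  structure(list(n_cycles = as.integer(n_cycles), fs = fs,
                 channels = as.character(channels),
                 min_walk_s = min_walk_s, min_rest_s = min_rest_s,
                 erd_lead_s = erd_lead_s, erd_ramp_s = erd_ramp_s,
                 erd_hold_s = erd_hold_s,
                 alpha_drop = alpha_drop, beta_drop = beta_drop,
                 alpha_amp = alpha_amp, beta_amp = beta_amp,
                 amp_mod = amp_mod,
                 noise_scale = noise_scale, walk_mod = walk_mod,
                 artifacts = artifacts, subject = subject,
                 seed = as.integer(seed)),
            class = "gi_synth_config")
}

#' Artifact rates for the synthetic generator
#'
#' @param blink_rate_per_min mean rate of blink-like low-frequency
#'   high-amplitude transients (Poisson).
#' @param blink_amp blink peak amplitude (uV).
#' @param flat_channels labels of channels to receive a flat (constant) fault.
#' @param flat_duration_s duration of each flat fault (s).
#' @param line_amp amplitude (uV) of added 60 Hz line-noise sinusoid.
#' @export
artifact_spec <- function(blink_rate_per_min = 0, blink_amp = 100,
                          flat_channels = character(0), flat_duration_s = 6,
                          line_amp = 0) {
  assert_that(blink_rate_per_min >= 0 && line_amp >= 0 && flat_duration_s >= 0,
              "artifact rates must be non-negative")
  structure(list(blink_rate_per_min = blink_rate_per_min,
                 blink_amp = blink_amp,
                 flat_channels = as.character(flat_channels),
                 flat_duration_s = flat_duration_s,
                 line_amp = line_amp),
            class = "gi_artifact_spec")
}

new_session <- function(data, fs, channel_labels, timeline, meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 timeline = timeline, meta = meta),
            class = "gi_session")
}

#' @export
print.gi_session <- function(x, ...) {
  cat(sprintf("<gi_session> %d ch x %d samples @ %g Hz (%.1f s), %d gait cycles\n",
              nrow(x$data), ncol(x$data), x$fs, session_duration(x),
              n_cycles(x$timeline)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

session_duration <- function(session) ncol(session$data) / session$fs

# 1/f-shaped broadband noise via spectral shaping, unit SD. The FFT runs
# at a padded highly-composite length (mixed-radix fft degrades badly on
# lengths with large prime factors); the first n samples are kept.
noise_one_over_f <- function(n, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 1))             # flat below 1 Hz, 1/f above
  y <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n)] / m
  y / sd_pop(y)
}

# slow positive amplitude envelope (~0.2 Hz) with relative SD rel_sd,
# floored well above zero
slow_envelope <- function(n, fs, rel_sd) {
  if (rel_sd <= 0) return(rep(1, n))
  k <- max(4, ceiling(n / fs * 0.4) + 2)
  coarse <- stats::rnorm(k)
  env <- stats::spline(seq(0, 1, length.out = k), coarse,
                       xout = seq(0, 1, length.out = n))$y
  env <- env / sd_pop(env) * rel_sd
  pmax(1 + env, 0.1)
}

# ERD amplitude envelope: 1 at baseline, ramping to sqrt(1 - drop) starting
# lead_s before each event, held until hold_s after, released over ramp_s
erd_envelope <- function(t, events, lead_s, ramp_s, hold_s, drop) {
  env <- rep(1, length(t))
  if (drop <= 0 || !length(events)) return(env)
  s <- sqrt(1 - drop)
  for (ev in events) {
    t0 <- ev - lead_s                       # ramp-down onset
    t1 <- min(ev, t0 + ramp_s)              # full depth reached
    t2 <- ev + hold_s                       # release onset
    t3 <- t2 + ramp_s
    seg <- rep(1, length(t))
    dn <- t >= t0 & t < t1
    seg[dn] <- 1 + (s - 1) * (t[dn] - t0) / (t1 - t0)
    seg[t >= t1 & t < t2] <- s
    up <- t >= t2 & t < t3
    seg[up] <- s + (1 - s) * (t[up] - t2) / ramp_s
    env <- pmin(env, seg)
  }
  env
}

#' Generate a synthetic gait-session EEG recording
#'
#' Produces a multichannel session whose background is 1/f broadband noise
#' plus band-limited alpha (10 Hz) and beta (20 Hz) oscillators, with
#' pre-movement ERD envelopes applied to the oscillators around every gait
#' start and stop event, a small ~1 Hz rhythmic broadband modulation during
#' walking, and optional injected artifacts. The ground-truth event timeline
#' is attached, so every downstream stage can be tested without recorded
#' data.
#'
#' @param config a [synth_config()].
#' @return A `gi_session` with `n_cycles` starts and stops and all state
#'   durations at or above the configured minima.
#' @examples
#' s <- generate_session(synth_config(n_cycles = 2, seed = 7))
#' s$timeline
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "gi_synth_config"))
  with_rng(config$seed, {
    nc <- config$n_cycles
    rest_d <- stats::runif(nc + 1, config$min_rest_s, config$min_rest_s + 3)
    walk_d <- stats::runif(nc, config$min_walk_s, config$min_walk_s + 3)
    starts <- numeric(nc); stops <- numeric(nc)
    t_cur <- rest_d[1]
    for (i in seq_len(nc)) {
      starts[i] <- t_cur
      t_cur <- t_cur + walk_d[i]
      stops[i] <- t_cur
      t_cur <- t_cur + rest_d[i + 1]
    }
    duration <- t_cur
    fs <- config$fs
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    events <- sort(c(starts, stops))
    env_a <- erd_envelope(t, events, config$erd_lead_s, config$erd_ramp_s,
                          config$erd_hold_s, config$alpha_drop)
    env_b <- erd_envelope(t, events, config$erd_lead_s, config$erd_ramp_s,
                          config$erd_hold_s, config$beta_drop)
    walking <- rep(FALSE, n)
    for (i in seq_len(nc)) walking[t >= starts[i] & t < stops[i]] <- TRUE

    # shared cortical sources projected with per-channel weights and
    # phases (volume conduction with non-uniform topographies), plus
    # per-channel independent background. Channel pairs come out strongly
    # correlated, as in recorded EEG, yet no component is rank-one, so
    # common-average referencing attenuates rather than cancels the
    # oscillators.
    n_ch <- length(config$channels)
    bg_srcs <- rbind(noise_one_over_f(n, fs), noise_one_over_f(n, fs),
                     noise_one_over_f(n, fs))
    Wb <- matrix(stats::runif(n_ch * 3, 0.2, 1), nrow = n_ch)
    mod_a <- slow_envelope(n, fs, config$amp_mod %||% 0)
    mod_b <- slow_envelope(n, fs, config$amp_mod %||% 0)
    # oscillator sources reach every channel with non-uniform gains and a
    # moderate phase spread (<= pi/2): pairwise covariances stay positive,
    # so inter-channel correlations are high as in referenced EEG, while
    # the phase spread keeps the instantaneous channel mean from absorbing
    # the rhythm, so common-average referencing attenuates but does not
    # cancel the oscillators
    w_a <- stats::runif(n_ch, 0.6, 1.2)
    w_b <- stats::runif(n_ch, 0.6, 1.2)
    lag_a <- stats::runif(1, 0, 2 * pi) + stats::runif(n_ch, 0, pi / 2)
    lag_b <- stats::runif(1, 0, 2 * pi) + stats::runif(n_ch, 0, pi / 2)
    osc_env_a <- config$alpha_amp * env_a * mod_a
    osc_env_b <- config$beta_amp * env_b * mod_b
    mod_walk <- 1 + config$walk_mod * sin(2 * pi * 1.0 * t +
                                          stats::runif(1, 0, 2 * pi))
    data <- matrix(0, nrow = n_ch, ncol = n)
    for (ch in seq_len(n_ch)) {
      gain <- stats::runif(1, 0.8, 1.2)
      shared <- drop(Wb[ch, ] %*% bg_srcs)
      shared <- shared / sd_pop(shared)
      bg <- config$noise_scale * (sqrt(0.75) * shared +
                                  sqrt(0.25) * noise_one_over_f(n, fs))
      if (config$walk_mod > 0) bg[walking] <- bg[walking] * mod_walk[walking]
      data[ch, ] <- gain * bg +
        w_a[ch] * osc_env_a * sin(2 * pi * 10 * t + lag_a[ch]) +
        w_b[ch] * osc_env_b * sin(2 * pi * 20 * t + lag_b[ch])
    }
    timeline <- derive_anchor_points(event_timeline(starts, stops),
                                     end_time = duration)
    session <- new_session(data, fs, config$channels, timeline,
                           meta = list(subject = config$subject,
                                       generator = "gaitintent synthetic",
                                       seed = config$seed))
    a <- config$artifacts
    if (a$blink_rate_per_min > 0 || length(a$flat_channels) || a$line_amp > 0) {
      session <- inject_artifacts(session, a, seed = config$seed + 1L)
    }
    session
  })
}

#' Inject band-limited event-related desynchronization into a signal matrix
#'
#' Extracts the requested band by exact FFT masking, applies the ERD
#' amplitude envelope (linear ramp to `sqrt(1 - drop)` starting `lead_s`
#' before each event, held `hold_s` after it), and adds the modulated band
#' back to the untouched out-of-band residual. With `drop = 0` the input is
#' returned unchanged.
#'
#' @param data channels x samples numeric matrix (a single channel may be
#'   given as a vector).
#' @param fs sampling rate (Hz).
#' @param events event times (s).
#' @param band_hz length-2 numeric band edges, inside `(0, fs/2)`.
#' @param lead_s seconds before each event at which the drop begins.
#' @param drop fractional band power reduction in `[0, 1]`.
#' @param ramp_s,hold_s envelope ramp length and post-event hold (s).
#' @return Matrix (or vector) of the same shape.
#' @export
inject_band_erd <- function(data, fs, events, band_hz, lead_s, drop,
                            ramp_s = 0.5, hold_s = 0.5) {
  assert_that(drop >= 0 && drop <= 1, "drop must lie in [0, 1]")
  assert_that(length(band_hz) == 2 && band_hz[1] > 0 && band_hz[2] <= fs / 2 &&
                band_hz[1] < band_hz[2],
              "band edges must lie inside (0, fs/2]")
  vec <- !is.matrix(data)
  if (vec) data <- matrix(data, nrow = 1)
  if (drop == 0 || !length(events)) return(if (vec) drop(data) else data)
  n <- ncol(data)
  t <- (seq_len(n) - 1) / fs
  env <- erd_envelope(t, events, lead_s, ramp_s, hold_s, drop)
  m <- stats::nextn(n, c(2, 3, 5))          # composite FFT length
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f <- pmin(f, fs - f)
  mask <- as.numeric(f >= band_hz[1] & f < band_hz[2])
  out <- data
  for (ch in seq_len(nrow(data))) {
    xp <- c(data[ch, ], numeric(m - n))
    xb <- Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE))[seq_len(n)] / m
    out[ch, ] <- data[ch, ] - xb + env * xb
  }
  if (vec) drop(out) else out
}

#' Inject artifacts into a session
#'
#' Adds blink-like transients (300 ms raised-cosine pulses, frontal-weighted),
#' flat-channel faults (a constant run replacing the signal), and 60 Hz line
#' noise. Blink times and flat-fault extents are recorded in `session$meta`.
#'
#' @param session a `gi_session`.
#' @param spec an [artifact_spec()].
#' @param seed integer seed for artifact placement.
#' @return The modified session.
#' @export
inject_artifacts <- function(session, spec, seed = 1L) {
  stopifnot(inherits(session, "gi_session"), inherits(spec, "gi_artifact_spec"))
  with_rng(seed, {
    fs <- session$fs
    n <- ncol(session$data)
    dur <- n / fs
    if (spec$blink_rate_per_min > 0) {
      n_blinks <- stats::rpois(1, spec$blink_rate_per_min * dur / 60)
      times <- sort(stats::runif(n_blinks, 0.5, dur - 0.5))
      pulse_n <- round(0.3 * fs)
      pulse <- spec$blink_amp * 0.5 * (1 - cos(2 * pi * seq_len(pulse_n) / pulse_n))
      w <- ifelse(session$channel_labels %in% c("FCz", "Cz"), 1,
                  ifelse(session$channel_labels %in% c("C3", "C4"), 0.7, 0.4))
      for (tb in times) {
        i0 <- round(tb * fs)
        idx <- i0:(i0 + pulse_n - 1)
        idx <- idx[idx >= 1 & idx <= n]
        session$data[, idx] <- session$data[, idx] +
          outer(w, pulse[seq_along(idx)])
      }
      session$meta$blinks <- times
    }
    if (spec$line_amp > 0) {
      t <- (seq_len(n) - 1) / fs
      line <- spec$line_amp * sin(2 * pi * 60 * t + stats::runif(1, 0, 2 * pi))
      session$data <- session$data + matrix(line, nrow = nrow(session$data),
                                            ncol = n, byrow = TRUE)
      session$meta$line_amp <- spec$line_amp
    }
    # flat faults last: a railed electrode outputs a constant regardless
    # of ambient line pickup
    if (length(spec$flat_channels)) {
      flat_n <- round(spec$flat_duration_s * fs)
      assert_that(flat_n <= n, "flat fault longer than the recording")
      faults <- list()
      for (lab in spec$flat_channels) {
        ch <- match(lab, session$channel_labels)
        assert_that(!is.na(ch), "unknown flat-fault channel ", lab)
        i0 <- sample.int(n - flat_n + 1, 1)
        session$data[ch, i0:(i0 + flat_n - 1)] <- session$data[ch, i0]
        faults[[lab]] <- c(start_s = (i0 - 1) / fs,
                           end_s = (i0 + flat_n - 1) / fs)
      }
      session$meta$flat_faults <- faults
    }
    session
  })
}
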