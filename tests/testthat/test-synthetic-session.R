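test_that("generated timelines have the configured cycle counts and state minima", {
  for (seed in c(1, 17, 23)) {
    nc <- sample(2:12, 1)
    s <- generate_session(synth_config(n_cycles = nc, seed = seed))
    tl <- s$timeline
    expect_length(tl$starts, nc)
    expect_length(tl$stops, nc)
    expect_length(tl$walk_anchors, nc)
    expect_length(tl$rest_anchors, nc)
    # alternation and minima
    expect_true(all(tl$stops - tl$starts >= 5))
    if (nc > 1) expect_true(all(tl$starts[-1] - tl$stops[-nc] >= 5))
    expect_true(tl$starts[1] >= 5)
    # anchors strictly between their flanking events
    expect_true(all(tl$walk_anchors > tl$starts & tl$walk_anchors < tl$stops))
    dur <- ncol(s$data) / s$fs
    expect_true(all(tl$rest_anchors > tl$stops))
    expect_true(all(tl$rest_anchors < c(tl$starts[-1], dur)))
    expect_true(all(is.finite(s$data)))
  }
})

test_that("identical config and seed give bit-identical sessions", {
  cfg <- synth_config(n_cycles = 3, seed = 99)
  expect_identical(generate_session(cfg), generate_session(cfg))
})

test_that("invalid generator configs are rejected", {
  expect_error(synth_config(n_cycles = 0), "n_cycles")
  expect_error(synth_config(fs = -100), "fs")
  expect_error(synth_config(channels = character(0)), "channel")
  expect_error(synth_config(alpha_drop = 1.5), "drops")
})

test_that("null construction: zero drops leave pre-event and rest band power equal", {
  cfg <- synth_config(n_cycles = 6, alpha_drop = 0, beta_drop = 0,
                      amp_mod = 0, walk_mod = 0, noise_scale = 0, seed = 4)
  s <- generate_session(cfg)
  fs <- s$fs
  win <- function(t0) s$data[1, (round((t0 - 1) * fs) + 1):round(t0 * fs)]
  pre <- mean(vapply(s$timeline$starts, function(t0)
    band_power_welch(win(t0), fs, c(8, 13)), numeric(1)))
  rest <- mean(vapply(s$timeline$rest_anchors, function(t0)
    band_power_welch(win(t0), fs, c(8, 13)), numeric(1)))
  expect_lt(abs(pre - rest) / rest, 0.05)
})

test_that("injected ERD depth is recovered by an independent PSD oracle", {
  for (drop in c(0.25, 0.5, 0.75)) {
    cfg <- synth_config(n_cycles = 5, alpha_drop = drop, beta_drop = 0,
                        amp_mod = 0, walk_mod = 0, noise_scale = 0,
                        erd_lead_s = 1.5, seed = 11)
    s <- generate_session(cfg)
    fs <- s$fs
    win <- function(t0) s$data[1, (round((t0 - 1) * fs) + 1):round(t0 * fs)]
    pre <- mean(vapply(s$timeline$starts, function(t0)
      band_power_welch(win(t0), fs, c(8, 13)), numeric(1)))
    rest <- mean(vapply(s$timeline$rest_anchors, function(t0)
      band_power_welch(win(t0), fs, c(8, 13)), numeric(1)))
    expect_rel_equal(pre / rest, 1 - drop, 0.10)
  }
})

test_that("inject_band_erd: identity, full suppression, and envelope depth", {
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  events <- c(10, 20, 30)
  expect_identical(inject_band_erd(x, fs, events, c(8, 13), 1.5, 0), x)

  y1 <- inject_band_erd(x, fs, events, c(8, 13), 1.5, 1)
  base <- band_power_fft(x[1:(2 * fs)], fs, c(8, 13))
  final <- band_power_fft(y1[(round(19.75 * fs) + 1):(20 * fs)], fs, c(8, 13))
  expect_lt(final / base, 0.01)

  y <- inject_band_erd(x, fs, events, c(8, 13), 1.5, 0.5)
  # amplitude right at the event: envelope holds at sqrt(0.5)
  at_event <- max(abs(y[round(19.9 * fs):round(20.05 * fs)]))
  expect_rel_equal(at_event, sqrt(0.5), 0.05)
  # out-of-band content untouched
  x2 <- x + sin(2 * pi * 30 * t)
  y2 <- inject_band_erd(x2, fs, events, c(8, 13), 1.5, 0.5)
  expect_rel_equal(band_power_fft(y2[1:(40 * fs)], fs, c(28, 32)),
                   band_power_fft(x2, fs, c(28, 32)), 0.01)
  expect_error(inject_band_erd(x, fs, events, c(8, 200), 1.5, 0.5), "band")
})

test_that("inject_artifacts: identity at zero rates, line power, flat faults", {
  s <- generate_session(synth_config(n_cycles = 2, seed = 8))
  s0 <- inject_artifacts(s, artifact_spec(), seed = 3)
  expect_identical(s0$data, s$data)

  a <- 5
  sl <- inject_artifacts(s, artifact_spec(line_amp = a), seed = 3)
  p_before <- band_power_fft(s$data[1, ], s$fs, c(59, 61))
  p_after <- band_power_fft(sl$data[1, ], s$fs, c(59, 61))
  expect_rel_equal(p_after - p_before, a^2 / 2, 0.05)

  sf <- inject_artifacts(s, artifact_spec(flat_channels = "Pz",
                                          flat_duration_s = 6), seed = 3)
  bc <- detect_bad_channels(sf)
  expect_true("Pz" %in% bc$bad)
  expect_match(bc$log$rejected_channels$rule[
    bc$log$rejected_channels$channel == "Pz"], "flat")
  expect_error(inject_artifacts(s, artifact_spec(flat_channels = "Pz",
                                                 flat_duration_s = 1e5),
                                seed = 1), "longer than the recording")
})
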