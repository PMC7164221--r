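fs_hi <- 500
t_hi <- (0:(10 * fs_hi - 1)) / fs_hi

test_that("resampling halves the sample count and preserves passband amplitude", {
  s <- mk_session(rbind(sin(2 * pi * 5 * t_hi), sin(2 * pi * 200 * t_hi)),
                  fs_hi)
  r <- resample_session(s, 250)
  expect_true(abs(ncol(r$data) - 2500) <= 1)
  expect_equal(r$fs, 250)
  # 5 Hz passband amplitude within 1%
  expect_rel_equal(max(abs(r$data[1, 500:2000])), 1, 0.01)
  # 200 Hz sits above the new Nyquist: residual power <= 1% of input power
  expect_lt(mean(r$data[2, 500:2000]^2) / 0.5, 0.01)
  expect_error(resample_session(r, 500), "upsampling")
})

test_that("1 Hz FIR high-pass removes DC, keeps 10 Hz, attenuates drift", {
  s <- mk_session(rbind(rep(5, length(t_hi)), sin(2 * pi * 10 * t_hi),
                        sin(2 * pi * 0.1 * t_hi)), fs_hi)
  h <- highpass_1hz(s)
  expect_lt(abs(mean(h$data[1, ])) / 5, 1e-6)
  expect_rel_equal(max(abs(h$data[2, 2000:3000])), 1, 0.01)
  atten_db <- 20 * log10(max(abs(h$data[3, 2000:3000])))
  expect_lt(atten_db, -20)
})

test_that("60 Hz notch suppresses line noise and spares neighbours", {
  s <- mk_session(rbind(sin(2 * pi * 60 * t_hi), sin(2 * pi * 10 * t_hi),
                        sin(2 * pi * 60 * t_hi) + sin(2 * pi * 10 * t_hi)),
                  fs_hi)
  nt <- notch_60(s)
  expect_lt(max(abs(nt$data[1, 2000:3000])), 0.10)
  expect_rel_equal(max(abs(nt$data[2, 2000:3000])), 1, 0.01)
  # mixture: 10 Hz survives, 60 Hz suppressed (periodogram oracle)
  p10 <- band_power_fft(nt$data[3, ], fs_hi, c(9, 11))
  p60 <- band_power_fft(nt$data[3, ], fs_hi, c(59, 61))
  expect_rel_equal(p10, 0.5, 0.05)
  expect_lt(p60, 0.01)
  expect_error(notch_60(mk_session(matrix(rnorm(200), 2), fs = 100)),
               "Nyquist")
})

test_that("bad-channel rules: flat run, identical channels, independent channel", {
  set.seed(10)
  s <- mk_correlated_session(n_ch = 4, n_s = 10, seed = 10)
  s$data[4, 1000:(1000 + 6 * s$fs)] <- s$data[4, 1000]
  bc <- detect_bad_channels(s, flat_s = 5)
  expect_identical(bc$bad, "ch4")
  expect_match(bc$log$rejected_channels$rule, "flat")

  # two identical noise channels correlate at 1: neither flagged
  x <- rnorm(2500)
  s2 <- mk_session(rbind(x, x), 250)
  expect_length(detect_bad_channels(s2)$bad, 0)

  # an independent-noise channel among correlated channels is flagged
  s3 <- mk_correlated_session(n_ch = 4, n_s = 10, seed = 11)
  s3$data[2, ] <- rnorm(ncol(s3$data))
  bc3 <- detect_bad_channels(s3)
  expect_identical(bc3$bad, "ch2")
  expect_match(bc3$log$rejected_channels$rule, "r")
  # each rejected channel cites exactly one rule
  expect_equal(anyDuplicated(bc3$log$rejected_channels$channel), 0)
})

test_that("ASR passes clean data, removes bursts, and is exact at infinite cutoff", {
  set.seed(4)
  fs <- 500
  d <- matrix(rnorm(8 * 30 * fs), nrow = 8)
  s <- mk_session(d, fs)
  r <- asr_repair(s, cutoff_sd = 10, calib_s = 10)
  expect_lt(sqrt(mean((r$session$data - d)^2)) / sqrt(mean(d^2)), 0.05)
  rInf <- asr_repair(s, cutoff_sd = Inf, calib_s = 10)
  expect_equal(rInf$session$data, d, tolerance = 1e-12)

  d2 <- d
  bidx <- 10000:(10000 + round(0.2 * fs))     # 200 ms burst at 50x SD
  d2[3, bidx] <- d2[3, bidx] + 50 * rnorm(length(bidx))
  rb <- asr_repair(mk_session(d2, fs), cutoff_sd = 10, calib_s = 10)
  rms_in <- sqrt(mean(d2[3, bidx]^2))
  rms_out <- sqrt(mean(rb$session$data[3, bidx]^2))
  expect_gt(1 - rms_out / rms_in, 0.80)
  flank <- c(7000:9000, 12000:14000)
  expect_lt(sqrt(mean((rb$session$data[3, flank] - d2[3, flank])^2)) /
              sqrt(mean(d2[3, flank]^2)), 0.05)
  expect_gt(nrow(rb$log$repaired_segments), 0)
  expect_error(asr_repair(mk_session(d[, 1:100], fs), calib_s = 10),
               "shorter")
})

test_that("common averaging zeroes the per-sample channel mean and is idempotent", {
  set.seed(5)
  d <- matrix(rnorm(4 * 1000), nrow = 4)
  s <- mk_session(d, 250)
  c1 <- common_average_reference(s)
  expect_lt(max(abs(colMeans(c1$data))), 1e-10)
  c2 <- common_average_reference(c1)
  expect_equal(c2$data, c1$data, tolerance = 1e-12)
  # opposite-sign pair is already average-free
  v <- rnorm(1000)
  sp <- common_average_reference(mk_session(rbind(v, -v), 250))
  expect_equal(sp$data[1, ], v, tolerance = 1e-12)
  expect_error(common_average_reference(mk_session(matrix(v, 1), 250)),
               "2 channels")
})

test_that("full chain rejects the flat channel, cuts line power, logs repairs", {
  cfg <- synth_config(n_cycles = 10, seed = 21,
                      artifacts = artifact_spec(blink_rate_per_min = 4,
                                                flat_channels = "Pz",
                                                flat_duration_s = 6,
                                                line_amp = 10))
  s <- generate_session(cfg)
  p60_in <- band_power_fft(s$data[1, ], s$fs, c(59.5, 60.5))
  pp <- preprocess_session(s)
  expect_true("Pz" %in% pp$log$rejected_channels$channel)
  expect_false("Pz" %in% pp$session$channel_labels)
  p60_out <- band_power_fft(pp$session$data[1, ], pp$session$fs, c(59.5, 60.5))
  expect_lt(p60_out / p60_in, 0.01)        # >= 20 dB line-power reduction
  expect_gt(nrow(pp$log$repaired_segments), 0)
  expect_match(pp$log$filters_applied[1], "resample")
  expect_match(pp$log$filters_applied[length(pp$log$filters_applied)],
               "common_average")
  # determinism of the whole chain
  pp2 <- preprocess_session(generate_session(cfg))
  expect_identical(pp$session$data, pp2$session$data)
})
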