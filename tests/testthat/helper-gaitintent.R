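# shared fixtures and independent oracles

# bare session around a data matrix (bypasses the generator)
mk_session <- function(data, fs, labs = paste0("ch", seq_len(nrow(data))),
                       starts = numeric(0), stops = numeric(0)) {
  gaitintent:::new_session(data, fs, labs, event_timeline(starts, stops))
}

# one-sided FFT band power oracle: for a*sin(2*pi*f*t), returns a^2/2
band_power_fft <- function(x, fs, band) {
  n <- length(x)
  sp <- (Mod(stats::fft(x)) / n)^2
  f <- (seq_len(n) - 1) * fs / n
  2 * sum(sp[f >= band[1] & f < band[2] & f <= fs / 2])
}

# Welch-style PSD band power oracle (averaged modified periodograms)
band_power_welch <- function(x, fs, band, seg_s = 1) {
  n <- length(x)
  seg <- round(seg_s * fs)
  starts <- seq(1, n - seg + 1, by = floor(seg / 2))
  mean(vapply(starts, function(i0)
    band_power_fft(x[i0:(i0 + seg - 1)], fs, band), numeric(1)))
}

# a session with strongly correlated channels built from a shared source
mk_correlated_session <- function(n_ch = 4, n_s = 10, fs = 250, seed = 1) {
  set.seed(seed)
  n <- n_s * fs
  shared <- stats::rnorm(n)
  data <- t(vapply(seq_len(n_ch), function(i)
    shared + 0.3 * stats::rnorm(n), numeric(n)))
  mk_session(data, fs)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
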