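new_cleaning_log <- function() {
  structure(list(rejected_channels = data.frame(channel = character(0),
                                                rule = character(0)),
                 repaired_segments = data.frame(start_s = numeric(0),
                                               end_s = numeric(0),
                                               n_components = integer(0)),
                 filters_applied = character(0)),
            class = "gi_cleaning_log")
}

log_filter <- function(log, desc) {
  log$filters_applied <- c(log$filters_applied, desc)
  log
}

#' @export
print.gi_cleaning_log <- function(x, ...) {
  cat("<gi_cleaning_log>\n  filters:",
      paste(x$filters_applied, collapse = " -> "), "\n")
  if (nrow(x$rejected_channels))
    cat("  rejected:", paste(x$rejected_channels$channel, "(",
                             x$rejected_channels$rule, ")", collapse = ", "), "\n")
  cat("  repaired segments:", nrow(x$repaired_segments), "\n")
  invisible(x)
}

#' Downsample a session with anti-alias filtering
#'
#' Integer-factor decimation: a zero-phase FIR low-pass at the new Nyquist
#' frequency is applied before index decimation, so passband amplitudes are
#' preserved and content above the new Nyquist is suppressed. Event times
#' are in seconds and are unchanged.
#'
#' @param session a `gi_session`.
#' @param target_fs target rate (Hz); must divide `session$fs`.
#' @return The resampled session.
#' @export
resample_session <- function(session, target_fs = 250) {
  stopifnot(inherits(session, "gi_session"))
  assert_that(target_fs <= session$fs, "upsampling is not supported")
  if (target_fs == session$fs) return(session)
  q <- session$fs / target_fs
  assert_that(abs(q - round(q)) < 1e-9,
              "fs must be an integer multiple of target_fs")
  q <- round(q)
  b <- signal::fir1(100, (1 / q) * 0.9)
  n <- ncol(session$data)
  keep <- seq(1, n, by = q)
  out <- matrix(0, nrow = nrow(session$data), ncol = length(keep))
  for (ch in seq_len(nrow(session$data))) {
    y <- signal::filtfilt(b, session$data[ch, ])
    out[ch, ] <- y[keep]
  }
  new_session(out, target_fs, session$channel_labels, session$timeline,
              session$meta)
}

# windowed-sinc linear-phase FIR high-pass, delay compensated.
# transition band roughly 0.5-1.5 Hz around the 1 Hz cutoff.
fir_highpass <- function(fs, cutoff = 1, transition = 1) {
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 1) n_taps <- n_taps + 1     # even order -> odd length
  b <- as.numeric(signal::fir1(n_taps, cutoff / (fs / 2), type = "high"))
  b - sum(b) / length(b)                         # exact zero DC gain
}

apply_fir <- function(x, b) {
  # single-pass linear-phase filtering with group-delay compensation;
  # anti-symmetric reflection padding keeps every retained sample at full
  # filter support, so edge transients never enter the output
  b <- as.numeric(b)
  delay <- (length(b) - 1) / 2
  n <- length(x)
  pad <- min(delay, n - 1)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::fftfilt(b, c(xp, numeric(delay)))
  y[(delay + pad + 1):(delay + pad + n)]
}

#' High-pass filter at 1 Hz (DC-drift removal)
#'
#' Linear-phase windowed-sinc FIR with the group delay compensated; DC gain
#' is exactly zero.
#' @param session a `gi_session`.
#' @export
highpass_1hz <- function(session) {
  stopifnot(inherits(session, "gi_session"))
  b <- fir_highpass(session$fs)
  for (ch in seq_len(nrow(session$data)))
    session$data[ch, ] <- apply_fir(session$data[ch, ], b)
  session
}

#' Notch filter at 60 Hz
#'
#' Second-order IIR notch (quality factor 30, ~2 Hz bandwidth) applied
#' forward and backward for zero phase.
#' @param session a `gi_session`.
#' @param f0 notch frequency (Hz).
#' @param q quality factor.
#' @export
notch_60 <- function(session, f0 = 60, q = 30) {
  stopifnot(inherits(session, "gi_session"))
  assert_that(session$fs > 2 * f0, "Nyquist below the notch frequency")
  w0 <- 2 * pi * f0 / session$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  for (ch in seq_len(nrow(session$data)))
    session$data[ch, ] <- signal::filtfilt(b, a, session$data[ch, ])
  session
}

#' Detect bad channels
#'
#' A channel is flagged if it holds a constant value for more than `flat_s`
#' seconds, or if its maximum absolute Pearson correlation with every other
#' channel falls below `corr_thresh`. Each flagged channel cites exactly one
#' rule (the flat rule takes precedence).
#'
#' @param session a `gi_session` with at least two channels.
#' @param flat_s flat-run duration threshold (s).
#' @param corr_thresh correlation threshold.
#' @return list with `bad` (labels) and `log` (a cleaning log).
#' @export
detect_bad_channels <- function(session, flat_s = 5, corr_thresh = 0.7) {
  stopifnot(inherits(session, "gi_session"))
  assert_that(nrow(session$data) >= 2, "need at least two channels")
  log <- new_cleaning_log()
  labs <- session$channel_labels
  flat_n <- flat_s * session$fs
  flat <- vapply(seq_along(labs), function(ch) {
    r <- rle(diff(session$data[ch, ]) == 0)
    any(r$values & r$lengths + 1 > flat_n)
  }, logical(1))
  C <- abs(suppressWarnings(stats::cor(t(session$data))))
  diag(C) <- NA
  C[is.na(C)] <- 0
  maxcor <- apply(C, 1, max)
  lowcor <- maxcor < corr_thresh & !flat
  bad <- labs[flat | lowcor]
  log$rejected_channels <- data.frame(
    channel = c(labs[flat], labs[lowcor]),
    rule = c(rep(sprintf("flat > %g s", flat_s), sum(flat)),
             rep(sprintf("max |r| < %g", corr_thresh), sum(lowcor))))
  list(bad = bad, log = log)
}

drop_channels <- function(session, bad) {
  keep <- !(session$channel_labels %in% bad)
  assert_that(sum(keep) >= 2, "fewer than two channels left after rejection")
  session$data <- session$data[keep, , drop = FALSE]
  session$channel_labels <- session$channel_labels[keep]
  session
}

# lowest-variance contiguous stretch, scanned in 1 s hops
default_calib_selector <- function(data, fs, calib_s) {
  n <- ncol(data)
  win <- round(calib_s * fs)
  assert_that(win <= n, "recording shorter than the calibration window")
  starts <- seq(1, n - win + 1, by = max(1, round(fs)))
  v <- vapply(starts, function(i0)
    sum(apply(data[, i0:(i0 + win - 1), drop = FALSE], 1, stats::var)),
    numeric(1))
  i0 <- starts[which.min(v)]
  i0:(i0 + win - 1)
}

#' Artifact-subspace burst repair
#'
#' A simplified artifact subspace reconstruction: the covariance of an
#' artifact-light calibration segment (by default the lowest-variance
#' contiguous `calib_s` seconds) defines a principal-component basis and
#' per-component reference scales. The recording is scanned in 0.5 s
#' windows with 50\% overlap; within each window, components whose RMS
#' exceeds `cutoff_sd` times the calibration scale are removed and the
#' window is reconstructed from the remaining subspace, with raised-cosine
#' overlap-add. With `cutoff_sd = Inf` the input passes through exactly.
#'
#' @param session a `gi_session`.
#' @param cutoff_sd deviation threshold in calibration-SD units.
#' @param calib_s calibration segment length (s).
#' @param calib_selector optional function `(data, fs, calib_s) -> sample
#'   indices` overriding the default segment choice.
#' @param win_s sliding window length (s).
#' @return list with `session` (repaired) and `log`.
#' @export
asr_repair <- function(session, cutoff_sd = 10, calib_s = 60,
                       calib_selector = default_calib_selector,
                       win_s = 0.5) {
  stopifnot(inherits(session, "gi_session"))
  log <- new_cleaning_log()
  fs <- session$fs
  X <- session$data
  n <- ncol(X)
  idx_cal <- calib_selector(X, fs, calib_s)
  mu <- rowMeans(X[, idx_cal, drop = FALSE])
  C0 <- stats::cov(t(X[, idx_cal, drop = FALSE] - mu))
  eig <- eigen(C0, symmetric = TRUE)
  V <- eig$vectors
  ref_sd <- sqrt(pmax(eig$values, .Machine$double.eps))

  win <- round(win_s * fs)
  if (win %% 2 == 1) win <- win + 1
  hop <- win / 2
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  acc <- matrix(0, nrow = nrow(X), ncol = n)
  wacc <- numeric(n)
  flagged <- logical(n)
  starts <- seq(1, max(1, n - win + 1), by = hop)
  if (starts[length(starts)] + win - 1 < n)
    starts <- c(starts, n - win + 1)
  for (i0 in starts) {
    idx <- i0:(i0 + win - 1)
    W <- X[, idx, drop = FALSE] - mu
    Y <- crossprod(V, W)
    rms <- sqrt(rowMeans(Y^2))
    kill <- is.finite(cutoff_sd) & (rms > cutoff_sd * ref_sd)
    if (any(kill)) {
      Y[kill, ] <- 0
      flagged[idx] <- TRUE
      Wr <- V %*% Y
    } else Wr <- W
    acc[, idx] <- acc[, idx] + sweep(Wr + mu, 2, taper, `*`)
    wacc[idx] <- wacc[idx] + taper
  }
  ok <- wacc > 1e-12
  acc[, ok] <- sweep(acc[, ok, drop = FALSE], 2, wacc[ok], `/`)
  acc[, !ok] <- X[, !ok]
  session$data <- acc

  if (any(flagged)) {
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    seg_start <- (c(1, ends[-length(ends)] + 1)[r$values] - 1) / fs
    seg_end <- ends[r$values] / fs
    log$repaired_segments <- data.frame(start_s = seg_start, end_s = seg_end,
                                        n_components = NA_integer_)
  }
  log <- log_filter(log, sprintf("asr(cutoff_sd=%g)", cutoff_sd))
  list(session = session, log = log)
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across retained channels from every
#' channel, so the per-sample channel mean is zero. Idempotent.
#' @param session a `gi_session` with at least two channels.
#' @export
common_average_reference <- function(session) {
  stopifnot(inherits(session, "gi_session"))
  assert_that(nrow(session$data) >= 2, "common average needs >= 2 channels")
  session$data <- sweep(session$data, 2, colMeans(session$data))
  session
}

#' Full preprocessing chain
#'
#' Fixed order: resample to `target_fs`, 1 Hz FIR high-pass, 60 Hz notch,
#' bad-channel rejection (flat run and low-correlation rules), simplified
#' artifact-subspace burst repair, optional ICA-style cleaning hook, then
#' common-average re-referencing. The order and every rejection/repair is
#' recorded in the returned cleaning log.
#'
#' @param session a `gi_session`.
#' @param target_fs analysis rate (Hz).
#' @param flat_s,corr_thresh bad-channel rule parameters.
#' @param asr_cutoff_sd burst-repair threshold in SD units; `Inf` disables.
#' @param asr_calib_s calibration segment length (s); capped at half the
#'   recording when the recording is short.
#' @param ica_hook optional `function(session) session` applied between
#'   burst repair and re-referencing, where an independent-component
#'   cleaning step would sit; no decomposition is shipped.
#' @return list with `session` (cleaned) and `log` (a `gi_cleaning_log`).
#' @export
preprocess_session <- function(session, target_fs = 250, flat_s = 5,
                               corr_thresh = 0.7, asr_cutoff_sd = 10,
                               asr_calib_s = 60, ica_hook = NULL) {
  log <- new_cleaning_log()
  # detection statistics come from the unfiltered recording: filtering
  # smears a flat run over the filter support and erases the evidence the
  # flat rule needs. The flagged channels are removed at the usual point
  # in the chain, after the filters.
  bc <- detect_bad_channels(session, flat_s, corr_thresh)
  session <- resample_session(session, target_fs)
  log <- log_filter(log, sprintf("resample(%g Hz)", target_fs))
  session <- highpass_1hz(session)
  log <- log_filter(log, "fir_highpass(1 Hz)")
  session <- notch_60(session)
  log <- log_filter(log, "notch(60 Hz, Q=30)")
  log$rejected_channels <- bc$log$rejected_channels
  log <- log_filter(log, "bad_channel_rejection")
  if (length(bc$bad)) session <- drop_channels(session, bc$bad)
  calib_s <- min(asr_calib_s, floor(session_duration(session) / 2))
  rep <- asr_repair(session, cutoff_sd = asr_cutoff_sd, calib_s = calib_s)
  session <- rep$session
  log$repaired_segments <- rep$log$repaired_segments
  log <- log_filter(log, sprintf("asr(cutoff_sd=%g)", asr_cutoff_sd))
  if (!is.null(ica_hook)) {
    session <- ica_hook(session)
    log <- log_filter(log, "ica_hook")
  }
  session <- common_average_reference(session)
  log <- log_filter(log, "common_average_reference")
  list(session = session, log = log)
}
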