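#' Hjorth parameters of a signal window
#'
#' Activity is the (population) variance; mobility the ratio of the
#' standard deviation of the first difference to that of the signal, a
#' frequency proxy; complexity the ratio of the mobility of the first
#' difference to the mobility of the signal, a bandwidth proxy that equals
#' 1 for a pure sinusoid. The `"literal"` variant instead multiplies the
#' second-difference/first-difference SD ratio by the mobility, which
#' reduces to `sd(diff(diff(x))) / sd(x)`; it is provided as a
#' configuration switch but does not tend to 1 on a sinusoid.
#'
#' Derivatives are first differences without time scaling (the dt factors
#' cancel in both ratios). A constant window has zero activity and no
#' defined mobility or complexity; these are returned as `NA` with
#' `degenerate = TRUE` rather than silent `NaN`.
#'
#' @param x numeric window, length >= 3.
#' @param complexity `"standard"` or `"literal"`.
#' @return Named list: `activity`, `mobility`, `complexity`, `degenerate`.
#' @export
hjorth <- function(x, complexity = c("standard", "literal")) {
  complexity <- match.arg(complexity)
  assert_that(length(x) >= 3, "Hjorth parameters need at least 3 samples")
  s0 <- sd_pop(x)
  act <- s0^2
  if (s0 == 0)
    return(list(activity = 0, mobility = NA_real_, complexity = NA_real_,
                degenerate = TRUE))
  d1 <- diff(x)
  d2 <- diff(d1)
  s1 <- sd_pop(d1)
  s2 <- sd_pop(d2)
  mob <- s1 / s0
  cpx <- if (s1 == 0) NA_real_
  else if (complexity == "standard") (s2 / s1) / mob
  else (s2 / s1) * mob
  list(activity = act, mobility = mob, complexity = cpx,
       degenerate = is.na(cpx))
}

#' Sliding sub-windows over an epoch
#'
#' Cuts an epoch into `win_s`-second windows advancing by `step_s` seconds:
#' `floor((L - win_s)/step_s) + 1` windows in temporal order. Start samples
#' are rounded per window, so non-integer sample steps (e.g. 50 ms at
#' 250 Hz = 12.5 samples) keep the exact nominal count: one-second epochs
#' give 11 sub-windows, 1.5 s give 21, 2 s give 31.
#'
#' @param n_samples epoch length in samples.
#' @param fs sampling rate (Hz).
#' @param win_s sub-window length (s).
#' @param step_s step between sub-window onsets (s).
#' @return List of integer index vectors.
#' @export
slide_subwindows <- function(n_samples, fs, win_s = 0.5, step_s = 0.05) {
  L_s <- n_samples / fs
  assert_that(win_s <= L_s + 1e-9, "sub-window longer than the epoch")
  count <- floor((L_s - win_s) / step_s + 1e-9) + 1
  win_n <- round(win_s * fs)
  lapply(seq_len(count) - 1, function(k) {
    i0 <- round(k * step_s * fs)
    (i0 + 1):(i0 + win_n)
  })
}

#' Build the sub-band Hjorth feature matrix for an epoch set
#'
#' Every epoch is decomposed per channel with a 5-level db4 wavelet
#' transform; the configured detail levels (by default level 3 = beta and
#' level 4 = alpha at 250 Hz) are reconstructed as band-limited signals and
#' divided into sliding sub-windows, whose three Hjorth parameters form the
#' feature vector: `n_subwindows x n_bands x 3` features per channel,
#' concatenated over channels. One-second epochs on eight channels give
#' 66 features per channel, 528 in total.
#'
#' @param epochset a `gi_epochset`.
#' @param bands named integer vector of detail levels, e.g.
#'   `c(beta = 3, alpha = 4)`.
#' @param win_s,step_s sub-window length and step (s).
#' @param wavelet mother wavelet name.
#' @param complexity Hjorth complexity variant (see [hjorth()]).
#' @return A `gi_features` object: `values` (epochs x features),
#'   `descriptors` (channel, band, subwindow, parameter per column),
#'   `labels`, `anchors`, plus `row_flags` marking epochs that contained a
#'   degenerate (constant) sub-window.
#' @export
build_features <- function(epochset, bands = c(beta = 3, alpha = 4),
                           win_s = 0.5, step_s = 0.05, wavelet = "db4",
                           complexity = "standard") {
  stopifnot(inherits(epochset, "gi_epochset"))
  assert_that(!is.null(names(bands)) && all(nzchar(names(bands))),
              "bands must be a named vector of detail levels")
  n_ep <- length(epochset$epochs)
  n_samp <- ncol(epochset$epochs[[1]])
  for (ep in epochset$epochs)
    assert_that(ncol(ep) == n_samp, "epochs differ in length")
  wins <- slide_subwindows(n_samp, epochset$fs, win_s, step_s)
  n_win <- length(wins)
  chans <- epochset$channel_labels
  params <- c("activity", "mobility", "complexity")
  desc <- expand.grid(parameter = params, subwindow = seq_len(n_win),
                      band = names(bands), channel = chans,
                      stringsAsFactors = FALSE)
  desc <- desc[, c("channel", "band", "subwindow", "parameter")]
  n_feat <- nrow(desc)

  values <- matrix(NA_real_, nrow = n_ep, ncol = n_feat)
  row_flags <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    col <- 0L
    for (ch in seq_along(chans)) {
      dec <- dwt5(epochset$epochs[[e]][ch, ], wavelet = wavelet)
      for (b in seq_along(bands)) {
        band_sig <- reconstruct_band(dec, bands[[b]])
        for (w in seq_len(n_win)) {
          hp <- hjorth(band_sig[wins[[w]]], complexity = complexity)
          values[e, col + 1:3] <- c(hp$activity, hp$mobility, hp$complexity)
          if (isTRUE(hp$degenerate)) row_flags[e] <- TRUE
          col <- col + 3L
        }
      }
    }
  }
  structure(list(values = values, descriptors = desc,
                 labels = epochset$labels, anchors = epochset$anchors,
                 problem = epochset$problem, window = epochset$window,
                 row_flags = row_flags),
            class = "gi_features")
}

#' @export
print.gi_features <- function(x, ...) {
  cat(sprintf("<gi_features> %d epochs x %d features (%s%s)\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$problem)) paste0(x$problem, ", ") else "",
              if (!is.null(x$window)) x$window$name else "unwindowed"))
  invisible(x)
}
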