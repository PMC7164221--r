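#' Epoch window specification
#'
#' Offsets are in seconds relative to the anchoring event; negative means
#' before the event, so `window_spec(-1, 0)` is the one-second window ending
#' at the event ("[-1 0]").
#' @param start_offset_s,end_offset_s window offsets (s), start < end.
#' @export
window_spec <- function(start_offset_s, end_offset_s) {
  assert_that(start_offset_s < end_offset_s,
              "window start offset must precede end offset")
  structure(list(start_offset_s = start_offset_s,
                 end_offset_s = end_offset_s,
                 name = sprintf("[%g %g]", start_offset_s, end_offset_s)),
            class = "gi_window_spec")
}

#' Detect gait events from an in-sole pressure trace
#'
#' A gait start is the onset of sustained pressure activity after a quiet
#' period, a stop the onset of sustained quiet after activity. Activity is
#' `trace > threshold`; runs shorter than `debounce_s` are merged into their
#' neighbours, which guarantees alternation. An all-quiet trace yields an
#' empty timeline.
#'
#' @param trace numeric pressure trace.
#' @param fs sampling rate (Hz).
#' @param threshold activity threshold (same units as `trace`).
#' @param debounce_s minimum state duration (s).
#' @return A `gi_timeline`.
#' @export
detect_events_from_pressure <- function(trace, fs, threshold,
                                        debounce_s = 1) {
  assert_that(all(is.finite(trace)), "pressure trace must be finite")
  active <- trace > threshold
  deb_n <- max(1L, round(debounce_s * fs))
  repeat {
    r <- rle(active)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < deb_n)
    short <- short[short > 1]           # leading state is kept as-is
    if (!length(short)) break
    i <- short[1]
    ends <- cumsum(r$lengths)
    idx <- (ends[i] - r$lengths[i] + 1):ends[i]
    active[idx] <- !active[idx]         # merge into the preceding run
  }
  d <- diff(c(FALSE, active))
  rises <- which(d == 1)
  falls <- which(d == -1)
  if (length(active) && active[1]) {
    # activity from sample one has no observed onset; drop it and its offset
    rises <- rises[rises != 1]
    if (length(falls)) falls <- falls[-1]
  }
  falls <- falls[falls > (if (length(rises)) rises[1] else Inf)]
  rises <- rises[seq_len(min(length(rises), length(falls) + 1L))]
  event_timeline((rises - 1) / fs, (falls - 1) / fs)
}

#' Extract balanced labelled epochs for one binary problem
#'
#' For `rest_vs_start`, positive epochs are anchored at gait starts and
#' negative epochs at rest anchors; for `walk_vs_stop`, at gait stops and
#' walk anchors. Epochs that would extend past the recording are dropped
#' with a warning; classes are then trimmed to equal size by dropping the
#' latest surplus anchors; finally any cross-class overlapping pair
#' (half-open intervals) is dropped and counts re-balanced. Every epoch has
#' `round((end - start) * fs)` samples.
#'
#' @param session a `gi_session` whose timeline has derived anchors.
#' @param spec a [window_spec()].
#' @param problem `"rest_vs_start"` or `"walk_vs_stop"`.
#' @return A `gi_epochset`.
#' @export
extract_epochs <- function(session, spec,
                           problem = c("rest_vs_start", "walk_vs_stop")) {
  stopifnot(inherits(session, "gi_session"), inherits(spec, "gi_window_spec"))
  problem <- match.arg(problem)
  tl <- session$timeline
  if (!length(tl$walk_anchors) && !length(tl$rest_anchors))
    tl <- derive_anchor_points(tl, end_time = session_duration(session))
  if (problem == "rest_vs_start") {
    pos_t <- tl$starts; pos_lab <- "start"
    neg_t <- tl$rest_anchors; neg_lab <- "rest"
  } else {
    pos_t <- tl$stops; pos_lab <- "stop"
    neg_t <- tl$walk_anchors; neg_lab <- "walk"
  }
  fs <- session$fs
  n <- ncol(session$data)
  len <- round((spec$end_offset_s - spec$start_offset_s) * fs)

  cut_one <- function(anchor) {
    i0 <- round((anchor + spec$start_offset_s) * fs) + 1
    if (i0 < 1 || i0 + len - 1 > n) return(NULL)
    session$data[, i0:(i0 + len - 1), drop = FALSE]
  }
  gather <- function(times, lab) {
    ep <- lapply(times, cut_one)
    keep <- !vapply(ep, is.null, logical(1))
    if (any(!keep))
      warning(sum(!keep), " ", lab,
              " epoch(s) extended past the recording and were dropped")
    list(epochs = ep[keep], anchors = times[keep], label = lab)
  }
  pos <- gather(pos_t, pos_lab)
  neg <- gather(neg_t, neg_lab)

  balance <- function(a, b) {
    k <- min(length(a$epochs), length(b$epochs))
    a$epochs <- a$epochs[seq_len(k)]; a$anchors <- a$anchors[seq_len(k)]
    b$epochs <- b$epochs[seq_len(k)]; b$anchors <- b$anchors[seq_len(k)]
    list(a, b)
  }
  bl <- balance(pos, neg); pos <- bl[[1]]; neg <- bl[[2]]

  build <- function(pos, neg) {
    structure(list(
      epochs = c(pos$epochs, neg$epochs),
      labels = factor(c(rep(pos$label, length(pos$epochs)),
                        rep(neg$label, length(neg$epochs))),
                      levels = c(neg$label, pos$label)),
      anchors = c(pos$anchors, neg$anchors),
      window = spec, fs = fs, problem = problem,
      channel_labels = session$channel_labels),
      class = "gi_epochset")
  }
  es <- build(pos, neg)
  chk <- validate_no_overlap(es)
  if (!chk$pass) {
    bad <- unique(c(chk$pairs[, 1], chk$pairs[, 2]))
    warning(length(bad), " overlapping epoch(s) dropped")
    keep <- setdiff(seq_along(es$epochs), bad)
    pos_k <- keep[keep <= length(pos$epochs)]
    neg_k <- keep[keep > length(pos$epochs)] - length(pos$epochs)
    pos$epochs <- pos$epochs[pos_k]; pos$anchors <- pos$anchors[pos_k]
    neg$epochs <- neg$epochs[neg_k]; neg$anchors <- neg$anchors[neg_k]
    bl <- balance(pos, neg); pos <- bl[[1]]; neg <- bl[[2]]
    es <- build(pos, neg)
  }
  assert_that(length(es$epochs) > 0, "no usable epochs for ", problem,
              " with window ", spec$name)
  es
}

#' Validate cross-class temporal disjointness of an epoch set
#'
#' Epoch supports are half-open intervals `[onset, offset)`; epochs of
#' different classes must not intersect (sharing a single boundary point is
#' allowed).
#' @param epochset a `gi_epochset`.
#' @return list with `pass` (logical) and `pairs` (matrix of offending
#'   epoch index pairs).
#' @export
validate_no_overlap <- function(epochset) {
  stopifnot(inherits(epochset, "gi_epochset"))
  w <- epochset$window
  lo <- epochset$anchors + w$start_offset_s
  hi <- epochset$anchors + w$end_offset_s
  lab <- epochset$labels
  pairs <- NULL
  k <- length(lo)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      j <- (i + 1):k
      hit <- j[lab[j] != lab[i] & lo[j] < hi[i] & lo[i] < hi[j]]
      if (length(hit)) pairs <- rbind(pairs, cbind(i, hit))
    }
  }
  list(pass = is.null(pairs),
       pairs = if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs)
}

#' @export
print.gi_epochset <- function(x, ...) {
  cat(sprintf("<gi_epochset> %s, window %s: %d epochs (%s), %d ch x %d samples @ %g Hz\n",
              x$problem, x$window$name, length(x$epochs),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              nrow(x$epochs[[1]]), ncol(x$epochs[[1]]), x$fs))
  invisible(x)
}
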