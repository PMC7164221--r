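#' Gait event timeline
#'
#' An ordered set of gait `start` and `stop` event times (seconds from
#' recording start). Events must strictly alternate beginning with a start,
#' and each stop must follow its start. Walk and rest anchor points (the
#' midpoints used to sample steady-state epochs) are attached by
#' [derive_anchor_points()].
#'
#' @param starts,stops ascending numeric event times in seconds.
#' @return An object of class `gi_timeline`.
#' @seealso [derive_anchor_points()], [generate_session()]
#' @export
event_timeline <- function(starts, stops) {
  starts <- as.numeric(starts)
  stops <- as.numeric(stops)
  validate_alternation(starts, stops)
  structure(list(starts = starts, stops = stops,
                 walk_anchors = numeric(0), rest_anchors = numeric(0)),
            class = "gi_timeline")
}

# check strict start/stop alternation, reporting the offending event index
# in the merged chronological sequence
validate_alternation <- function(starts, stops) {
  assert_that(!is.unsorted(starts, strictly = TRUE) || length(starts) < 2,
              "start times must be strictly ascending")
  assert_that(!is.unsorted(stops, strictly = TRUE) || length(stops) < 2,
              "stop times must be strictly ascending")
  lab <- c(rep("start", length(starts)), rep("stop", length(stops)))
  t <- c(starts, stops)
  o <- order(t)
  lab <- lab[o]
  expected <- rep(c("start", "stop"), length.out = length(lab))
  bad <- which(lab != expected)
  if (length(bad)) {
    stop_data("events do not alternate start/stop: event ", bad[1],
              " is '", lab[bad[1]], "' but '", expected[bad[1]],
              "' was expected")
  }
  assert_that((length(starts) - length(stops)) %in% c(0L, 1L),
              "timeline has ", length(starts), " starts but ",
              length(stops), " stops")
  invisible(TRUE)
}

#' Derive walk and rest anchor points
#'
#' A walk anchor is the midpoint between a gait start and the following stop;
#' a rest anchor is the midpoint between a stop and the following start.
#' When `end_time` is supplied the trailing rest interval (last stop to the
#' end of the recording) also contributes a rest anchor, so a session of
#' `n` complete gait cycles yields `n` walk and `n` rest anchors.
#'
#' @param timeline a [event_timeline()].
#' @param end_time optional recording end time (s); enables the trailing
#'   rest anchor.
#' @return The timeline with `walk_anchors` and `rest_anchors` filled in.
#' @export
derive_anchor_points <- function(timeline, end_time = NULL) {
  stopifnot(inherits(timeline, "gi_timeline"))
  starts <- timeline$starts
  stops <- timeline$stops
  n_pair <- min(length(starts), length(stops))
  walk <- if (n_pair) (starts[seq_len(n_pair)] + stops[seq_len(n_pair)]) / 2 else numeric(0)
  rest <- numeric(0)
  if (length(stops) >= 1 && length(starts) >= 2) {
    n_gap <- min(length(stops), length(starts) - 1L)
    rest <- (stops[seq_len(n_gap)] + starts[seq_len(n_gap) + 1L]) / 2
  }
  if (!is.null(end_time) && length(stops) &&
      end_time > stops[length(stops)]) {
    rest <- c(rest, (stops[length(stops)] + end_time) / 2)
  }
  timeline$walk_anchors <- walk
  timeline$rest_anchors <- rest
  timeline
}

#' @export
print.gi_timeline <- function(x, ...) {
  cat(sprintf("<gi_timeline> %d starts, %d stops, %d walk / %d rest anchors\n",
              length(x$starts), length(x$stops),
              length(x$walk_anchors), length(x$rest_anchors)))
  invisible(x)
}

n_cycles <- function(timeline) min(length(timeline$starts), length(timeline$stops))
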