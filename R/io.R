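#' Write a session to EDF plus a tab-separated event sidecar
#'
#' The signal goes to a European Data Format file (16-bit quantization); the
#' event timeline goes to a two-column TSV sidecar (`onset_s`, `label` with
#' labels `start`/`stop`), onsets at 1 ms resolution.
#'
#' @param session a `gi_session`.
#' @param path EDF output path.
#' @param events_path sidecar output path; defaults to `path` with a
#'   `.events.tsv` extension.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path,
                          events_path = paste0(tools::file_path_sans_ext(path),
                                               ".events.tsv")) {
  stopifnot(inherits(session, "gi_session"))
  write_edf(session$data, session$fs, session$channel_labels, path,
            subject = session$meta$subject %||% "X")
  write_events(session$timeline, events_path)
  invisible(path)
}

write_events <- function(timeline, path) {
  df <- data.frame(
    onset_s = round(c(timeline$starts, timeline$stops), 3),
    label = c(rep("start", length(timeline$starts)),
              rep("stop", length(timeline$stops))))
  df <- df[order(df$onset_s), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_events <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("onset_s", "label") %in% names(df)),
              "event sidecar must have onset_s and label columns: ", path)
  bad <- which(!df$label %in% c("start", "stop"))
  if (length(bad))
    stop_data("event sidecar line ", bad[1] + 1L, ": unknown label '",
              df$label[bad[1]], "'")
  event_timeline(df$onset_s[df$label == "start"],
                 df$onset_s[df$label == "stop"])
}

#' Read a session from EDF plus its event sidecar
#'
#' @param path EDF file.
#' @param events_path tab-separated event sidecar with `onset_s` and `label`
#'   columns; labels restricted to `start` and `stop`. Non-alternating
#'   events raise an error naming the offending index.
#' @return A `gi_session` with anchors derived.
#' @export
read_session <- function(path,
                         events_path = paste0(tools::file_path_sans_ext(path),
                                              ".events.tsv")) {
  raw <- read_edf(path)
  timeline <- read_events(events_path)
  dur <- ncol(raw$data) / raw$fs
  assert_that(all(c(timeline$starts, timeline$stops) <= dur + 1e-9),
              "event times extend past the recording end")
  timeline <- derive_anchor_points(timeline, end_time = dur)
  new_session(raw$data, raw$fs, raw$channel_labels, timeline,
              meta = list(subject = raw$subject, source = path))
}

#' Lint a session/sidecar pair
#'
#' @param path EDF file path.
#' @param events_path event sidecar path.
#' @return A character vector of problems (empty when the pair is valid).
#' @export
validate_session_files <- function(path, events_path) {
  problems <- character(0)
  raw <- tryCatch(read_edf(path), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  if (!file.exists(events_path))
    return(c(problems, paste0("no such file: ", events_path)))
  lines <- readLines(events_path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   c("onset_s", "label")))
    problems <- c(problems, paste0(events_path,
                                   ":1: header must be 'onset_s<TAB>label'"))
  labs <- character(0); onsets <- numeric(0)
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 2) {
      problems <- c(problems, paste0(events_path, ":", i, ": expected 2 fields"))
      next
    }
    onset <- suppressWarnings(as.numeric(f[1]))
    if (is.na(onset))
      problems <- c(problems, paste0(events_path, ":", i,
                                     ": non-numeric onset '", f[1], "'"))
    if (!f[2] %in% c("start", "stop"))
      problems <- c(problems, paste0(events_path, ":", i,
                                     ": unknown label '", f[2], "'"))
    else if (!is.na(onset)) { labs <- c(labs, f[2]); onsets <- c(onsets, onset) }
  }
  if (length(labs)) {
    o <- order(onsets)
    labs <- labs[o]
    expected <- rep(c("start", "stop"), length.out = length(labs))
    bad <- which(labs != expected)
    if (length(bad))
      problems <- c(problems, paste0(events_path, ": events do not alternate",
                                     " start/stop at event ", bad[1]))
    if (!is.null(raw)) {
      dur <- ncol(raw$data) / raw$fs
      late <- which(onsets > dur + 1e-9)
      if (length(late))
        problems <- c(problems,
                      paste0(events_path, ": event at ", onsets[late[1]],
                             " s lies past the recording end (", dur, " s)"))
    }
  }
  problems
}

#' Persist a feature matrix as TSV
#'
#' One row per epoch; first columns `label` and `anchor_s`, then one column
#' per feature named `<channel>.<band>.w<subwindow>.<parameter>` so the
#' descriptor of every feature is recoverable from the header row.
#' @param fm a `gi_features` object.
#' @param path output path.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "gi_features"))
  d <- fm$descriptors
  cols <- sprintf("%s.%s.w%02d.%s", d$channel, d$band, d$subwindow, d$parameter)
  df <- data.frame(label = as.character(fm$labels), anchor_s = fm$anchors,
                   check.names = FALSE)
  df[cols] <- as.data.frame(fm$values)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  feat_cols <- setdiff(names(df), c("label", "anchor_s"))
  parts <- strsplit(feat_cols, ".", fixed = TRUE)
  desc <- data.frame(
    channel = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    subwindow = as.integer(sub("^w", "", vapply(parts, `[`, "", 3))),
    parameter = vapply(parts, `[`, "", 4))
  structure(list(values = as.matrix(df[feat_cols]),
                 descriptors = desc,
                 labels = factor(df$label), anchors = df$anchor_s,
                 problem = NULL, window = NULL),
            class = "gi_features")
}

REPORT_REQUIRED <- c("meta", "problems")

#' Write / read an evaluation report (JSON)
#'
#' Reports round-trip losslessly at full numeric precision. A report missing
#' its confusion counts or metric blocks is rejected.
#' @param report a `gi_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  rep <- structure(rep, class = "gi_report")
  validate_report(rep)
  rep
}

validate_report <- function(report) {
  assert_that(all(REPORT_REQUIRED %in% names(report)),
              "incomplete report: needs ", paste(REPORT_REQUIRED, collapse = ", "))
  for (pname in names(report$problems)) {
    prob <- report$problems[[pname]]
    assert_that(!is.null(prob$windows) && length(prob$windows) > 0,
                "report problem '", pname, "' has no window blocks")
    for (wname in names(prob$windows)) {
      blk <- prob$windows[[wname]]
      assert_that(!is.null(blk$per_subject),
                  "report block ", pname, "/", wname, " lacks per-subject metrics")
      for (subj in blk$per_subject) {
        assert_that(all(c("TP", "TN", "FP", "FN") %in% names(subj$confusion %||% list())),
                    "report block ", pname, "/", wname,
                    " lacks confusion counts")
      }
    }
  }
  invisible(TRUE)
}

#' Read / write an experiment configuration (YAML)
#' @param config an `gi_experiment_config` (see [experiment_config()]).
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gi_experiment_config"))
  out <- unclass(config)
  out$bands <- as.list(out$bands)    # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}
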