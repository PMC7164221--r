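#' Experiment configuration
#'
#' One structured configuration drives the full chain: synthetic session
#' generation, preprocessing, segmentation into the two binary problems
#' under every window specification, sub-band Hjorth feature extraction,
#' redundancy-penalized selection, and cost-sensitive SVM cross-validation.
#'
#' @param windows list of length-2 numeric vectors `(start_offset_s,
#'   end_offset_s)` relative to the event; default the five study windows
#'   `[-1 1]`, `[-1.5 0.5]`, `[-2 0]`, `[-1.5 0]`, `[-1 0]`.
#' @param subwindow_len_s,subwindow_step_s Hjorth sub-window length and
#'   step (s).
#' @param bands named detail levels, default `c(beta = 3, alpha = 4)` at
#'   the 250 Hz analysis rate.
#' @param n_selected features kept by selection.
#' @param beta_penalty redundancy penalty exponent.
#' @param svm list with `gamma`, `cost_pos`, `cost_neg` (see [svm_spec()]).
#' @param cv_folds cross-validation folds (>= 2).
#' @param selection_scope `"per_fold"` (no leakage) or `"global"`.
#' @param complexity Hjorth complexity variant.
#' @param target_fs preprocessing analysis rate (Hz).
#' @param synth list of [synth_config()] overrides plus `n_subjects` and
#'   `n_sessions` (recording sessions pooled per subject; a subject's
#'   trials are the union of their sessions' gait cycles, emulating a
#'   protocol of ~140 cycles collected over repeated runs).
#' @param seed master seed; per-subject generator seeds are derived from it.
#' @export
experiment_config <- function(windows = list(c(-1, 1), c(-1.5, 0.5),
                                             c(-2, 0), c(-1.5, 0), c(-1, 0)),
                              subwindow_len_s = 0.5, subwindow_step_s = 0.05,
                              bands = c(beta = 3, alpha = 4),
                              n_selected = 20, beta_penalty = 1,
                              svm = list(gamma = NULL, cost_pos = 2,
                                         cost_neg = 1),
                              cv_folds = 10,
                              selection_scope = "per_fold",
                              complexity = "standard",
                              target_fs = 250,
                              synth = list(n_subjects = 3, n_sessions = 14,
                                           n_cycles = 10),
                              seed = 1L) {
  windows <- lapply(windows, as.numeric)
  for (w in windows) {
    assert_that(length(w) == 2 && w[1] < w[2],
                "each window must be (start, end) with start < end")
    assert_that(subwindow_len_s <= w[2] - w[1] + 1e-9,
                "sub-window longer than window ", sprintf("[%g %g]", w[1], w[2]))
  }
  assert_that(cv_folds >= 2, "cv_folds must be >= 2")
  bands <- stats::setNames(as.integer(unlist(bands)),
                           names(unlist(bands)))
  structure(list(windows = windows, subwindow_len_s = subwindow_len_s,
                 subwindow_step_s = subwindow_step_s, bands = bands,
                 n_selected = n_selected, beta_penalty = beta_penalty,
                 svm = svm, cv_folds = cv_folds,
                 selection_scope = selection_scope,
                 complexity = complexity, target_fs = target_fs,
                 synth = synth, seed = as.integer(seed)),
            class = "gi_experiment_config")
}

subject_seed <- function(seed, s) (abs(seed) %% 100000L) * 10000L + s

#' Pool feature matrices from several sessions of one subject
#'
#' Feature columns are z-scored within each session before the rows are
#' stacked. Recording sessions differ in overall signal state (electrode
#' gains, slow band-power level), and those session-level offsets are
#' shared by both classes of that session's epochs; without per-session
#' normalization a cross-validated classifier can key on session identity
#' instead of the event-related structure, which biases held-out
#' performance. The transform uses no class labels. Constant columns are
#' left centered at zero.
#'
#' @param fms list of `gi_features` from the same window/problem with
#'   identical feature descriptors.
#' @param standardize z-score within session (default) or stack raw rows.
#' @return A `gi_features` with pooled rows.
#' @export
pool_features <- function(fms, standardize = TRUE) {
  stopifnot(length(fms) >= 1)
  n_feat <- ncol(fms[[1]]$values)
  for (f in fms)
    assert_that(ncol(f$values) == n_feat, "feature spaces differ across sessions")
  vals <- lapply(fms, function(f) {
    v <- f$values
    if (standardize) {
      mu <- colMeans(v)
      sdv <- apply(v, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      v <- sweep(sweep(v, 2, mu), 2, sdv, `/`)
    }
    v
  })
  structure(list(values = do.call(rbind, vals),
                 descriptors = fms[[1]]$descriptors,
                 labels = factor(unlist(lapply(fms, function(f)
                   as.character(f$labels)))),
                 anchors = unlist(lapply(fms, `[[`, "anchors")),
                 problem = fms[[1]]$problem, window = fms[[1]]$window,
                 row_flags = unlist(lapply(fms, `[[`, "row_flags"))),
            class = "gi_features")
}

PROBLEMS <- c("rest_vs_start", "walk_vs_stop")
positive_class <- function(problem) if (problem == "rest_vs_start") "start" else "stop"

synth_config_for_session <- function(config, s, j) {
  args <- config$synth
  args$n_subjects <- NULL
  args$n_sessions <- NULL
  args$subject <- sprintf("SYN%02d", s)
  n_sess <- config$synth$n_sessions %||% 1
  args$seed <- subject_seed(config$seed, (s - 1L) * n_sess + j)
  do.call(synth_config, args)
}

#' Run the full synthetic-session experiment
#'
#' Generates one synthetic gait session per subject, runs the fixed
#' preprocessing chain, and for every (problem, window) combination
#' extracts balanced epochs, builds sub-band Hjorth features, and evaluates
#' a cost-sensitive RBF-SVM by stratified cross-validation with per-fold
#' selection. Per-subject metrics, cross-subject aggregates, and the
#' trans- vs pre-event window comparison are assembled into an evaluation
#' report; a run manifest captures the configuration, derived seeds, and
#' per-stage wall-clock so a run can be replayed exactly.
#'
#' @param config an [experiment_config()].
#' @param progress print per-subject progress.
#' @return list with `report` (a `gi_report`) and `manifest`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "gi_experiment_config"))
  t_all <- proc.time()[3]
  specs <- lapply(config$windows, function(w) window_spec(w[1], w[2]))
  wnames <- vapply(specs, function(s) s$name, "")
  n_sub <- config$synth$n_subjects %||% 14
  svm <- svm_spec(gamma = config$svm$gamma,
                  cost_pos = config$svm$cost_pos %||% 2,
                  cost_neg = config$svm$cost_neg %||% 1)
  timings <- c()
  blocks <- list()
  for (p in PROBLEMS) {
    blocks[[p]] <- stats::setNames(
      lapply(wnames, function(w) list(per_subject = list())), wnames)
  }
  n_sess <- config$synth$n_sessions %||% 1
  seeds <- list()
  subject_tags <- character(n_sub)
  for (s in seq_len(n_sub)) {
    t0 <- proc.time()[3]
    minutes <- 0
    cleaned <- vector("list", n_sess)
    sess_seeds <- integer(n_sess)
    for (j in seq_len(n_sess)) {
      scfg <- synth_config_for_session(config, s, j)
      sess_seeds[j] <- scfg$seed
      subject_tags[s] <- scfg$subject
      session <- generate_session(scfg)
      minutes <- minutes + session_duration(session) / 60
      cleaned[[j]] <- preprocess_session(session,
                                         target_fs = config$target_fs)$session
    }
    seeds[[s]] <- sess_seeds
    # channel rejection may differ between a subject's sessions; pooled
    # features use the channels retained in every session
    common <- Reduce(intersect, lapply(cleaned, `[[`, "channel_labels"))
    assert_that(length(common) >= 2, "fewer than two channels shared ",
                "across subject ", s, "'s sessions")
    cleaned <- lapply(cleaned, function(ss) {
      extra <- setdiff(ss$channel_labels, common)
      if (length(extra)) drop_channels(ss, extra) else ss
    })
    for (p in PROBLEMS) {
      for (wi in seq_along(specs)) {
        fms <- lapply(cleaned, function(ss) {
          es <- extract_epochs(ss, specs[[wi]], p)
          build_features(es, bands = config$bands,
                         win_s = config$subwindow_len_s,
                         step_s = config$subwindow_step_s,
                         complexity = config$complexity)
        })
        fm <- pool_features(fms)
        conf <- crossval(fm$values, fm$labels, positive_class(p),
                         folds = config$cv_folds,
                         seed = subject_seed(config$seed, s) + 1L,
                         spec = svm, k = config$n_selected,
                         beta = config$beta_penalty,
                         selection_scope = config$selection_scope)
        cc <- sum_confusions(conf)
        m <- classification_metrics(cc)
        rate <- trials_per_minute(cc$TN + cc$FP, minutes)
        blocks[[p]][[wnames[wi]]]$per_subject[[s]] <- list(
          subject = subject_tags[s], confusion = cc,
          accuracy = unname(m["accuracy"]),
          sensitivity = unname(m["sensitivity"]),
          specificity = unname(m["specificity"]),
          fp_per_min = fp_per_min(cc, rate),
          folds = conf)
      }
    }
    timings[s] <- proc.time()[3] - t0
    if (progress)
      message(sprintf("subject %d/%d done in %.1f s", s, n_sub, timings[s]))
  }
  trans <- wnames[vapply(specs, function(s) s$end_offset_s > 0, logical(1))]
  pre <- setdiff(wnames, trans)
  for (p in PROBLEMS) {
    acc_by_win <- lapply(blocks[[p]], function(blk)
      vapply(blk$per_subject, function(x) x$accuracy, numeric(1)))
    for (w in wnames) {
      per <- blocks[[p]][[w]]$per_subject
      agg <- lapply(c("accuracy", "sensitivity", "specificity", "fp_per_min"),
                    function(metric) {
                      v <- vapply(per, function(x) x[[metric]], numeric(1))
                      v <- v[!is.na(v)]
                      if (length(v) >= 2) as.list(aggregate_metrics(v))
                      else list(mean = mean(v), sd = NA_real_)
                    })
      names(agg) <- c("accuracy", "sensitivity", "specificity", "fp_per_min")
      blocks[[p]][[w]]$aggregate <- agg
    }
    if (length(trans) && length(pre) && n_sub >= 2) {
      blocks[[p]] <- c(blocks[[p]],
                       list(.comparison = compare_windows(acc_by_win, trans, pre)))
      cmp <- blocks[[p]]$.comparison
      blocks[[p]]$.comparison <- NULL
      attr(blocks[[p]], "comparison") <- cmp
    }
  }
  comparisons <- lapply(blocks, function(b) {
    cmp <- attr(b, "comparison")
    if (is.null(cmp)) NULL else as.list(cmp)
  })
  problems <- lapply(seq_along(blocks), function(i) {
    list(windows = lapply(blocks[[i]], function(w)
      list(per_subject = w$per_subject, aggregate = w$aggregate)),
      comparison = comparisons[[i]])
  })
  names(problems) <- names(blocks)
  report <- structure(list(
    meta = list(seed = config$seed, n_subjects = n_sub,
                package = "gaitintent",
                version = as.character(utils::packageVersion("gaitintent"))),
    problems = problems), class = "gi_report")
  manifest <- list(config = unclass(config), subject_seeds = seeds,
                   stage_seconds = timings,
                   total_seconds = proc.time()[3] - t_all,
                   versions = list(
                     gaitintent = as.character(utils::packageVersion("gaitintent")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  list(report = report, manifest = manifest)
}

#' @export
print.gi_report <- function(x, ...) {
  cat("<gi_report>", x$meta$n_subjects %||% "?", "subjects\n")
  for (p in names(x$problems)) {
    cat(sprintf("  %s:\n", p))
    for (w in names(x$problems[[p]]$windows)) {
      agg <- x$problems[[p]]$windows[[w]]$aggregate
      if (is.null(agg)) next
      cat(sprintf("    %-10s acc %5.2f +/- %4.2f  sens %5.2f  spec %5.2f  FP/min %.2f\n",
                  w, agg$accuracy$mean, agg$accuracy$sd,
                  agg$sensitivity$mean, agg$specificity$mean,
                  agg$fp_per_min$mean))
    }
  }
  invisible(x)
}
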