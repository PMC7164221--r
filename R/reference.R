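#' Reference per-subject classification metrics
#'
#' Published per-subject results from a nine-subject (seven healthy, two
#' trans-tibial amputee) eight-channel EEG gait-intention study: accuracy,
#' sensitivity and specificity (percent) for the `rest_vs_start` and
#' `walk_vs_stop` problems under the five window specifications. These
#' values serve as fixed inputs for the cross-subject aggregation and the
#' trans- vs pre-event window comparison; the package does not re-estimate
#' them.
#'
#' @return data.frame with columns `problem`, `subject`, `window`,
#'   `metric`, `value`.
#' @export
reference_subject_metrics <- function() {
  path <- system.file("extdata", "reference_subject_metrics.tsv",
                      package = "gaitintent")
  assert_that(nzchar(path), "reference table not installed")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference study-scale constants
#'
#' Totals from the same reference study: 1564 rest-or-walk trials over
#' 227.4 minutes of recording, the inputs to the trial-rate arithmetic.
#' @return list with `n_trials` and `minutes`.
#' @export
reference_study_constants <- function() {
  list(n_trials = 1564, minutes = 227.4)
}
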