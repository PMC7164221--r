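#' Absolute standardized rank-sum statistic
#'
#' Two-sample unpaired Wilcoxon (Mann-Whitney) statistic: U is computed
#' from midrank sums, standardized by its null mean `n1*n2/2` and
#' tie-corrected null standard deviation (normal approximation, no
#' continuity correction), and returned in absolute value. Identical
#' groups give 0; the statistic is symmetric in its arguments.
#'
#' @param values_a,values_b numeric samples from the two classes.
#' @return `|z|`, a non-negative scalar.
#' @export
ranksum_abs_z <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  assert_that(n1 > 0 && n2 > 0, "both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(values_a, values_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(0)     # everything tied: no separation
  abs((U - n1 * n2 / 2) / sqrt(sigma2))
}

# |z| for every column of X given a two-level grouping, vectorized ranking
col_ranksum_abs_z <- function(X, in_a) {
  apply(X, 2, function(col) ranksum_abs_z(col[in_a], col[!in_a]))
}

#' Mean absolute correlation with already-selected features
#'
#' Average over the selected columns of the absolute Pearson correlation
#' with the candidate. An empty selected set gives 0. A constant column's
#' correlation is undefined; its contribution is defined as 1 (maximally
#' redundant), so constant features are never preferred.
#'
#' @param candidate_col numeric vector.
#' @param selected_cols numeric matrix (columns = selected features), or
#'   `NULL`/zero columns for the empty set.
#' @export
mean_abs_corr <- function(candidate_col, selected_cols) {
  if (is.null(selected_cols) || NCOL(selected_cols) == 0) return(0)
  selected_cols <- as.matrix(selected_cols)
  assert_that(nrow(selected_cols) == length(candidate_col),
              "column length mismatch")
  r <- suppressWarnings(stats::cor(candidate_col, selected_cols))
  r[is.na(r)] <- 1
  mean(abs(r))
}

#' Greedy redundancy-penalized feature selection
#'
#' Features are scored by the absolute standardized rank-sum statistic of
#' the two classes ([ranksum_abs_z()]). The first pick is the top-scoring
#' feature; each subsequent pick maximizes `|z| * (1 - rho_bar)^beta`,
#' where `rho_bar` is the mean absolute correlation with the features
#' already selected, so features highly correlated with earlier picks are
#' penalized. `beta = 0` reduces to plain `|z|` top-k ranking. Ties break
#' deterministically toward the lower column index.
#'
#' @param matrix numeric samples x features matrix.
#' @param labels two-level class labels, one per row.
#' @param k number of features to select (capped at the feature count).
#' @param beta redundancy penalty exponent (>= 0).
#' @return A `gi_selection`: `selected` (ordered indices), `scores` (per
#'   feature `|z|`), `redundancy` (`rho_bar` of each pick at selection
#'   time), `k`.
#' @export
select_features <- function(matrix, labels, k = 20, beta = 1) {
  X <- as.matrix(matrix)
  labels <- as.factor(as.character(labels))
  assert_that(nlevels(labels) == 2, "labels must contain exactly two classes")
  assert_that(k >= 1, "k must be at least 1")
  in_a <- labels == levels(labels)[1]
  z <- col_ranksum_abs_z(X, in_a)
  p <- ncol(X)
  k <- min(k, p)
  selected <- integer(0)
  redundancy <- numeric(0)
  sum_abs_r <- numeric(p)         # running sum of |r| with selected set
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    rho_bar <- if (length(selected)) sum_abs_r / length(selected) else numeric(p)
    score <- if (length(selected)) z * pmax(1 - rho_bar, 0)^beta else z
    score[!remaining] <- -Inf
    pick <- which.max(score)      # which.max takes the first maximum
    selected <- c(selected, pick)
    redundancy <- c(redundancy, if (length(selected) > 1) rho_bar[pick] else 0)
    remaining[pick] <- FALSE
    r_new <- suppressWarnings(stats::cor(X, X[, pick]))
    r_new[is.na(r_new)] <- 1
    sum_abs_r <- sum_abs_r + abs(r_new)
  }
  structure(list(selected = selected, scores = z, redundancy = redundancy,
                 k = k),
            class = "gi_selection")
}

#' @export
print.gi_selection <- function(x, ...) {
  cat(sprintf("<gi_selection> %d features; top |z| = %.3f\n",
              length(x$selected), max(x$scores)))
  invisible(x)
}
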