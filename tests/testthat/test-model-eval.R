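test_that("SVM fits separable data perfectly and reduces to the unweighted machine", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 3), ncol = 2), matrix(rnorm(40, -3), ncol = 2))
  y <- rep(c("start", "rest"), each = 20)
  m <- train_cost_svm(X, y, "start", svm_spec(cost_pos = 5, cost_neg = 1))
  expect_equal(mean(predict(m, X) == y), 1)
  # equal costs == standard machine at that cost
  set.seed(2)
  Xo <- matrix(rnorm(200 * 4), ncol = 4)
  yo <- ifelse(rowSums(Xo[, 1:2]) + rnorm(200) > 0, "start", "rest")
  me <- train_cost_svm(Xo, yo, "start", svm_spec(gamma = 0.25, cost_pos = 1,
                                                 cost_neg = 1))
  ref <- e1071::svm(x = Xo, y = factor(yo), type = "C-classification",
                    kernel = "radial", gamma = 0.25, cost = 1, scale = FALSE)
  expect_identical(as.character(predict(me, Xo)),
                   as.character(predict(ref, Xo)))
  expect_error(train_cost_svm(Xo, rep("start", 200), "start"), "two classes")
})

test_that("raising the positive cost trades specificity for sensitivity", {
  set.seed(3)
  n_pos <- 50; n_neg <- 150
  gen <- function(n_pos, n_neg) {
    list(X = rbind(matrix(rnorm(2 * n_pos, 0.8), ncol = 2),
                   matrix(rnorm(2 * n_neg, 0), ncol = 2)),
         y = c(rep("start", n_pos), rep("rest", n_neg)))
  }
  tr <- gen(n_pos, n_neg)
  te <- gen(100, 300)
  m1 <- train_cost_svm(tr$X, tr$y, "start", svm_spec(cost_pos = 1, cost_neg = 1))
  m4 <- train_cost_svm(tr$X, tr$y, "start", svm_spec(cost_pos = 4, cost_neg = 1))
  cm1 <- gaitintent:::confusion_counts(te$y, predict(m1, te$X), "start")
  cm4 <- gaitintent:::confusion_counts(te$y, predict(m4, te$X), "start")
  s1 <- classification_metrics(cm1); s4 <- classification_metrics(cm4)
  expect_gte(s4["sensitivity"], s1["sensitivity"])
  expect_lte(s4["specificity"], s1["specificity"])
})

test_that("cross-validation partitions are stratified, disjoint, and exhaustive", {
  set.seed(4)
  X <- matrix(rnorm(100 * 8), 100, 8)
  y <- rep(c("start", "rest"), 50)
  assign <- gaitintent:::stratified_folds(factor(y), 10, seed = 5)
  expect_equal(as.integer(table(assign)), rep(10L, 10))
  for (f in 1:10)
    expect_equal(as.integer(table(y[assign == f])), c(5L, 5L))
  cc <- crossval(X, y, "start", folds = 10, seed = 5, k = 4)
  tot <- gaitintent:::sum_confusions(cc)
  expect_equal(tot$TP + tot$TN + tot$FP + tot$FN, 100)
  sizes <- vapply(cc, function(x) x$TP + x$TN + x$FP + x$FN, numeric(1))
  expect_true(all(sizes == 10))
  expect_error(crossval(X[1:12, ], y[1:12], "start", folds = 10), "folds")
})

test_that("a label-determining feature yields perfect folds; shuffled labels sit at chance", {
  set.seed(6)
  X <- matrix(rnorm(100 * 5), 100, 5)
  X[, 2] <- sample(c(rnorm(50, 3), rnorm(50, -3)))  # wide-margin feature
  y <- ifelse(X[, 2] > 0, "start", "rest")
  cc <- crossval(X, y, "start", folds = 10, seed = 7, k = 2)
  accs <- vapply(cc, function(x) classification_metrics(x)["accuracy"],
                 numeric(1))
  expect_true(all(accs == 100))

  y_shuf <- sample(rep(c("start", "rest"), 50))
  cc0 <- crossval(matrix(rnorm(100 * 30), 100, 30), y_shuf, "start",
                  folds = 10, seed = 8, k = 10)
  acc0 <- classification_metrics(gaitintent:::sum_confusions(cc0))["accuracy"]
  band <- 100 * (0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / 100))
  expect_gt(acc0, band[1])
  expect_lt(acc0, band[2])
})

test_that("metrics follow their defining arithmetic, with explicit undefined cases", {
  m <- classification_metrics(list(TP = 3, TN = 3, FP = 1, FN = 1))
  expect_equal(unname(m), c(75, 75, 75))
  m2 <- classification_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(m2), c(100, 100, 100))
  m3 <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_equal(unname(m3), c(50, 0, 100))
  m4 <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m4["sensitivity"]))
  # identity: accuracy = (sens*P + spec*N)/(P+N) on random confusions
  set.seed(9)
  for (i in 1:20) {
    cc <- as.list(setNames(sample(0:30, 4, replace = TRUE) + 1,
                           c("TP", "TN", "FP", "FN")))
    m <- classification_metrics(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(unname(m["accuracy"]),
                 unname((m["sensitivity"] * P + m["specificity"] * N) / (P + N)),
                 tolerance = 1e-9)
  }
})

test_that("trial-rate and FP/min arithmetic", {
  expect_equal(trials_per_minute(1564, 227.4), 6.88)
  expect_equal(trials_per_minute(60, 60), 1.00)
  expect_equal(trials_per_minute(0, 10), 0.00)
  expect_error(trials_per_minute(10, 0), "positive")
  expect_equal(fp_per_min(list(TP = 0, TN = 10, FP = 0, FN = 0), 6.88), 0)
  expect_equal(fp_per_min(list(TP = 0, TN = 79, FP = 21, FN = 0), 6.88),
               0.21 * 6.88, tolerance = 1e-12)
  expect_equal(fp_per_min(list(TP = 0, TN = 0, FP = 10, FN = 0), 6.88), 6.88)
  expect_error(fp_per_min(list(TP = 5, TN = 0, FP = 0, FN = 5), 6.88),
               "negative trials")
})

test_that("aggregation takes the arithmetic mean and sample SD", {
  v <- c(80.30, 75.19, 82.67, 69.81, 74.97, 77.63, 73.45, 71.96, 81.73)
  agg <- aggregate_metrics(v)
  expect_equal(unname(agg["mean"]), mean(v))
  expect_equal(unname(agg["sd"]), sd(v))
  expect_equal(unname(aggregate_metrics(c(70, 70, 70))["sd"]), 0)
  expect_error(aggregate_metrics(75), "two subjects")
})

test_that("window comparison: null pairs retain, dominating pairs reject", {
  acc <- list("[-1 1]" = c(70, 72, 74, 76), "[-1 0]" = c(70, 72, 74, 76))
  res <- compare_windows(acc, "[-1 1]", "[-1 0]")
  expect_equal(res$p_raw, 0.5, tolerance = 1e-12)
  expect_false(res$reject_raw)

  acc2 <- list("[-1 1]" = c(80.01, 82, 84.02, 86), "[-2 0]" = c(70, 72.02, 74, 76.01))
  res2 <- compare_windows(acc2, "[-1 1]", "[-2 0]")
  expect_true(res2$reject_raw && res2$reject_holm)

  # Holm family over all (trans, pre) pairs
  accs <- list("[-1 1]" = c(75, 76, 77), "[-1.5 0.5]" = c(74, 75, 76),
               "[-2 0]" = c(70, 71, 72), "[-1.5 0]" = c(73, 74, 75),
               "[-1 0]" = c(75, 76, 77))
  res3 <- compare_windows(accs, c("[-1 1]", "[-1.5 0.5]"),
                          c("[-2 0]", "[-1.5 0]", "[-1 0]"))
  expect_equal(nrow(res3), 6)
  expect_equal(res3$p_holm, p.adjust(res3$p_raw, "holm"))
  expect_error(compare_windows(acc, "[-9 9]", "[-1 0]"), "missing")
})
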