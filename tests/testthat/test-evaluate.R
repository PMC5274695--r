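test_that("confusion counts follow the one-vs-rest definitions", {
  truth <- rep(0:2, each = 10)
  # perfect predictor
  cc <- confusion_counts(truth, truth)
  expect_equal(cc$TP, rep(10, 3))
  expect_equal(cc$FP, rep(0, 3))
  expect_equal(cc$FN, rep(0, 3))
  expect_equal(cc$TN, rep(20, 3))
  # constant predictor
  cc0 <- confusion_counts(truth, rep(0L, 30), classes = 0:2)
  expect_equal(cc0[cc0$class == 0, c("TP", "FP", "TN", "FN")],
               data.frame(TP = 10L, FP = 20L, TN = 0L, FN = 0L),
               ignore_attr = TRUE)
  # counts always partition N
  expect_true(all(rowSums(cc0[, c("TP", "FP", "TN", "FN")]) == 30))
  expect_error(confusion_counts(0:2, 0:1), "equal length")
})

test_that("metrics reproduce the worked confusion-cell example", {
  cc <- data.frame(class = 1, TP = 50, FP = 10, TN = 30, FN = 10)
  m <- classification_metrics(cc)
  expect_equal(m$accuracy, 0.80, tolerance = 1e-4)
  expect_equal(m$ppv, 0.8333, tolerance = 1e-4)
  expect_equal(m$npv, 0.75, tolerance = 1e-4)
  expect_equal(m$sensitivity, 0.8333, tolerance = 1e-4)
  expect_equal(m$specificity, 0.75, tolerance = 1e-4)
  expect_equal(m$mcc, 0.5833, tolerance = 1e-4)
})

test_that("metrics hit their boundary values on perfect and inverted toys", {
  truth <- rep(0:1, each = 10)
  rp <- metrics_report(truth, truth)
  expect_equal(rp$overall_accuracy, 1)
  expect_true(all(abs(rp$per_class[, c("accuracy", "ppv", "npv",
                                       "sensitivity", "specificity",
                                       "mcc")] - 1) < 1e-12))
  inv <- metrics_report(truth, 1 - truth)
  expect_equal(inv$per_class$mcc, c(-1, -1))
  # degenerate denominators yield 0 with the flag set
  deg <- classification_metrics(confusion_counts(truth, rep(0L, 20),
                                                 classes = 0:1))
  expect_equal(deg$ppv[deg$class == 1], 0)
  expect_true(deg$degenerate[deg$class == 1])
})

test_that("metrics match a brute-force recount on random predictions", {
  set.seed(71)
  for (i in 1:10) {
    truth <- sample(0:2, 60, replace = TRUE)
    pred <- sample(0:2, 60, replace = TRUE)
    rp <- metrics_report(truth, pred)
    for (cl in 0:2) {
      want <- metrics_oracle(truth, pred, cl)
      row <- rp$per_class[rp$per_class$class == cl, ]
      got <- unlist(row[c("accuracy", "ppv", "npv", "sensitivity",
                          "specificity", "mcc")])
      expect_lt(max(abs(got - want)), 1e-12)
    }
    expect_equal(rp$overall_accuracy, mean(truth == pred),
                 tolerance = 1e-15)
  }
})

test_that("rank-statistic AUC equals exhaustive pair counting and pROC", {
  set.seed(72)
  for (i in 1:10) {
    truth <- sample(0:2, 18, replace = TRUE)
    if (length(unique(truth)) < 3) next
    scores <- matrix(round(rnorm(18 * 3), 1), 18, 3)   # induce ties
    auc <- roc_auc(truth, scores, classes = 0:2)
    for (j in 1:3) {
      expect_equal(auc[j], auc_pairs_oracle(truth == (j - 1), scores[, j]),
                   tolerance = 1e-12)
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = as.integer(truth == (j - 1)),
        predictor = scores[, j], direction = "<", quiet = TRUE)))
      expect_equal(auc[j], as.numeric(ref), tolerance = 1e-12)
    }
  }
})

test_that("AUC boundary cases and monotone-transform invariance", {
  truth <- rep(0:2, each = 4)
  onehot <- matrix(0, 12, 3)
  onehot[cbind(1:12, truth + 1)] <- 1
  expect_equal(unname(roc_auc(truth, onehot)), rep(1, 3))
  expect_equal(unname(roc_auc(truth, matrix(0.5, 12, 3))), rep(0.5, 3))
  set.seed(73)
  scores <- matrix(runif(36), 12, 3)
  expect_equal(roc_auc(truth, scores),
               roc_auc(truth, exp(5 * scores)), tolerance = 1e-12)
  expect_error(roc_auc(rep(0L, 5), matrix(0, 5, 1)), "two classes")
})

test_that("roc_points starts at the origin and ends at (1,1)", {
  set.seed(74)
  truth <- rep(0:1, each = 8)
  pts <- roc_points(truth, rnorm(16), positive = 1)
  expect_equal(unlist(pts[1, ]), c(FPR = 0, TPR = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(FPR = 1, TPR = 1))
  expect_true(all(diff(pts$FPR) >= 0) && all(diff(pts$TPR) >= 0))
})
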