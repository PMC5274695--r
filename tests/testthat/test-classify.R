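make_blobs <- function(n_per, d = 2, sep = 6, seed = 61) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d) + sep, n_per, d))
  list(x = x, y = rep(0:1, each = n_per))
}

test_that("linear SVM separates well-separated clouds and satisfies the dual constraint", {
  b <- make_blobs(20)
  m <- svm_fit(b$x, b$y, kernel = "linear")
  expect_equal(mean(svm_predict(m, b$x) == b$y), 1.0)
  # sum_i lambda_i y_i = 0 per binary subproblem
  expect_true(all(abs(svm_dual_residuals(m)) < 1e-6))
  expect_error(svm_fit(b$x, rep(1, 40)), "at least 2")
})

test_that("SVM predictions are invariant to training sample order", {
  set.seed(62)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(0:2, each = 20)
  x[y == 1, 1] <- x[y == 1, 1] + 3
  x[y == 2, 2] <- x[y == 2, 2] + 3
  perm <- sample.int(60)
  m1 <- svm_fit(x, y)
  m2 <- svm_fit(x[perm, ], y[perm])
  xt <- matrix(rnorm(30 * 3), 30, 3)
  expect_equal(svm_predict(m1, xt), svm_predict(m2, xt))
  # libsvm's SMO solver stops within a working tolerance, so decision
  # values agree only to that tolerance across training orders
  expect_equal(svm_decision(m1, xt), svm_decision(m2, xt),
               tolerance = 1e-2)
})

test_that("three-class one-vs-rest decisions pick the maximal machine", {
  set.seed(63)
  x <- matrix(rnorm(90 * 2), 90, 2)
  y <- rep(0:2, each = 30)
  x[y == 1, 1] <- x[y == 1, 1] + 5
  x[y == 2, 2] <- x[y == 2, 2] + 5
  m <- svm_fit(x, y)
  dv <- svm_decision(m, x)
  expect_identical(dim(dv), c(90L, 3L))
  expect_equal(svm_predict(m, x), m$classes[max.col(dv, "first")])
  expect_gt(mean(svm_predict(m, x) == y), 0.95)
})

test_that("fold plans partition indices with near-equal stratified sizes", {
  y <- rep(0:2, c(40, 30, 30))
  plan <- make_folds(y, k = 10, seed = 5)
  expect_identical(sort(unique(plan$fold)), 1:10)
  expect_length(plan$fold, 100)
  expect_equal(as.vector(table(plan$fold)), rep(10, 10))
  # remainder case: fold sizes differ by at most 1
  y2 <- rep(0:2, c(35, 30, 30))
  plan2 <- make_folds(y2, k = 10, seed = 5)
  expect_true(all(abs(table(plan2$fold) - 9.5) <= 0.5))
  # class proportions approximately preserved per fold
  tab <- table(plan$fold, y)
  expect_true(all(tab >= 2))
  expect_error(make_folds(rep(0:1, 3), k = 10), "at least k")
  # determinism
  expect_identical(make_folds(y, 10, seed = 5)$fold, plan$fold)
})

test_that("grouped folds keep augmentation siblings together", {
  y <- rep(rep(0:2, each = 5), each = 8)       # 15 groups x 8 variants
  groups <- rep(1:15, each = 8)
  plan <- make_folds(y, k = 5, groups = groups, seed = 3)
  for (g in unique(groups))
    expect_length(unique(plan$fold[groups == g]), 1)
  # mixing labels inside a group is rejected
  expect_error(make_folds(c(0, 1, 0, 0), k = 2, groups = c(1, 1, 2, 2)),
               "mixes labels")
})

test_that("cross_validate averages fold metrics and rejects leaky plans", {
  set.seed(64)
  patches <- generate_dataset(6, tiny_phantom_cfg(seed = 31))
  data <- build_data_matrix(patches, method = "dwt",
                            dsift_par = dsift_params(step = 8, bin_radius = 3))
  y <- as.integer(data[, 785])
  grp <- attr(data, "group")
  plan <- make_folds(y, k = 3, groups = grp, seed = 9)
  cfg <- cnn_config(epochs = 3L, fc_width = 16L, conv1_kernels = 4L,
                    conv2_kernels = 4L, seed = 2L)
  cv <- cross_validate(data, plan, cnn_cfg = cfg)
  expect_length(cv$per_fold, 3)
  accs <- vapply(cv$per_fold, `[[`, numeric(1), "overall_accuracy")
  expect_equal(cv$accuracy, mean(accs), tolerance = 1e-12)
  expect_true(cv$accuracy >= 0 && cv$accuracy <= 1)
  # a deliberately leaky plan is rejected
  bad <- plan
  bad$fold[1] <- (plan$fold[1] %% 3) + 1
  expect_error(cross_validate(data, bad, cnn_cfg = cfg), "leakage")
})
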