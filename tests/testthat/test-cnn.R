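# a small configuration used for fast structural checks
tiny_cnn_cfg <- function(epochs = 2L, ...)
  cnn_config(input_grid = 12L, conv1_kernels = 2L, conv1_size = 3L,
             conv2_kernels = 2L, conv2_size = 3L, fc_width = 5L,
             dropout = 0, epochs = epochs, batch_size = 8L, seed = 7L,
             ...)

test_that("softmax outputs are normalized probability rows", {
  cfg <- tiny_cnn_cfg()
  geo <- mammoband:::cnn_geometry(cfg)
  set.seed(51)
  wts <- mammoband:::init_weights(cfg)
  X <- matrix(rnorm(144 * 10), 144, 10)
  fw <- mammoband:::cnn_forward_pass(wts, cfg, geo, X)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  expect_lt(max(abs(colSums(fw$probs) - 1)), 1e-6)
  # zero weights give exactly uniform class probabilities
  wts0 <- lapply(wts, function(w) w * 0)
  fw0 <- mammoband:::cnn_forward_pass(wts0, cfg, geo, X)
  expect_lt(max(abs(fw0$probs - 1 / 3)), 1e-12)
})

test_that("a hand-set single convolution matches manual arithmetic", {
  # one 2x2 kernel on a 3x3 input, valid convolution + bias
  idx <- mammoband:::im2col_idx(3L, 3L, 1L, 2L)
  X <- matrix(as.numeric(1:9), 9, 1)      # 3x3 column-major
  W <- matrix(c(1, 10, 100, 1000), 4, 1)  # (kr, kc) column-major
  out <- mammoband:::conv_forward(X, idx, W, 5)
  img <- matrix(1:9, 3, 3)
  manual <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    manual[i, j] <- img[i, j] + 10 * img[i + 1, j] +
      100 * img[i, j + 1] + 1000 * img[i + 1, j + 1] + 5
  expect_equal(as.vector(out$Z), as.vector(manual))
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- tiny_cnn_cfg()
  geo <- mammoband:::cnn_geometry(cfg)
  set.seed(52)
  wts <- mammoband:::init_weights(cfg)
  X <- matrix(rnorm(144 * 4), 144, 4)
  y <- c(1L, 2L, 3L, 1L)
  fw <- mammoband:::cnn_forward_pass(wts, cfg, geo, X)
  gr <- mammoband:::cnn_backward_pass(wts, cfg, geo, fw, y)
  loss_at <- function(w) {
    f <- mammoband:::cnn_forward_pass(w, cfg, geo, X)
    mammoband:::cnn_loss(f$probs, y)
  }
  eps <- 1e-6
  for (nm in names(wts)) {
    w <- wts[[nm]]
    # probe a deterministic subset of entries per tensor
    probe <- unique(round(seq(1, length(w), length.out = min(20, length(w)))))
    for (i in probe) {
      wp <- wts; wp[[nm]][i] <- w[i] + eps
      wm <- wts; wm[[nm]][i] <- w[i] - eps
      ng <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      denom <- max(abs(ng), abs(gr[[nm]][i]), 1e-6)
      expect_lt(abs(ng - gr[[nm]][i]) / denom, 1e-4)
    }
  }
})

test_that("training is seed-reproducible and logs error = 100 - accuracy", {
  set.seed(53)
  x <- matrix(rnorm(30 * 144), 30, 144)
  y <- rep(0:2, each = 10)
  x[y == 1, 1:40] <- x[y == 1, 1:40] + 2
  x[y == 2, 100:144] <- x[y == 2, 100:144] - 2
  cfg <- tiny_cnn_cfg(epochs = 5L)
  m1 <- cnn_train(cfg, x, y)
  m2 <- cnn_train(cfg, x, y)
  expect_identical(m1$weights, m2$weights)
  expect_equal(m1$history$train_err, 100 - m1$history$train_acc,
               tolerance = 1e-12)
  expect_identical(nrow(m1$history), 5L)
  expect_error(cnn_train(cfg, x[y != 2, ], y[y != 2]), "every class")
})

test_that("the network memorizes a small separable phantom feature set", {
  set.seed(54)
  patches <- generate_dataset(20, phantom_config(seed = 77))
  data <- build_data_matrix(patches, method = "dwt",
                            augment_patches = FALSE)
  cfg <- cnn_config(epochs = 50L, seed = 5L)
  m <- cnn_train(cfg, data[, 1:784], as.integer(data[, 785]))
  expect_gte(tail(m$history$train_acc, 1), 95)
})

test_that("penultimate features have the declared shape and determinism", {
  set.seed(55)
  x <- matrix(rnorm(12 * 144), 12, 144)
  y <- rep(0:2, 4)
  m <- cnn_train(tiny_cnn_cfg(epochs = 1L), x, y)
  f1 <- penultimate_features(m, x)
  expect_identical(dim(f1), c(12L, 5L))
  expect_identical(f1, penultimate_features(m, x))
  expect_identical(f1[1, ], penultimate_features(m, x[c(1, 1), ])[2, ])
  probs <- cnn_forward(m, x)
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  expect_error(cnn_forward(m, x[, 1:100]), "expected")
})
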