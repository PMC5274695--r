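test_that("dsift geometry, determinism and degenerate input", {
  set.seed(41)
  b <- matrix(runif(64 * 64), 64, 64)
  d <- dsift(b)
  expect_identical(nrow(d), 128L)
  expect_identical(ncol(d), 144L)        # 12 x 12 grid: step 4, radius 5
  expect_true(all(d >= 0))
  expect_identical(unclass(d), unclass(dsift(b)))   # deterministic
  # constant band: zero gradients, zero descriptors by convention
  expect_true(all(dsift(matrix(0.3, 64, 64)) == 0))
  expect_error(dsift(matrix(0, 10, 10)), "too small")
})

test_that("descriptor entries respect the clamped renormalization bound", {
  set.seed(42)
  for (i in 1:5) {
    d <- dsift(matrix(runif(64 * 64), 64, 64))
    nrm <- sqrt(colSums(d^2))
    expect_true(all(nrm < 1 + 1e-9))
    # entries exceed 0.2 only by the renormalization of clamped vectors
    expect_true(all(d <= 0.25))
  }
})

test_that("180-degree rotation preserves the multiset of descriptor norms", {
  set.seed(43)
  b <- matrix(runif(64 * 64), 64, 64)
  n1 <- sort(sqrt(colSums(dsift(b)^2)))
  n2 <- sort(sqrt(colSums(dsift(rot180(b))^2)))
  expect_lt(max(abs(n1 - n2)), 1e-10)
})

test_that("band statistics match the brute-force moment oracle", {
  set.seed(44)
  for (K in c(2, 7, 50)) {
    d <- matrix(rexp(128 * K), 128, K)
    d[5, ] <- 2                      # a zero-variance row
    s <- band_statistics(d)
    expect_identical(dim(unclass(s)), c(128L, 6L))
    expect_lt(max(abs(unclass(s) - stats_oracle(d))), 1e-10)
  }
  expect_error(band_statistics(matrix(0, 128, 1)), "at least 2")
})

test_that("band statistics reproduce hand-computed values and conventions", {
  d <- matrix(0, 128, 4)
  d[1, ] <- 1:4
  s <- band_statistics(d)
  expect_equal(unname(s[1, c("mean", "maximum", "energy", "sd")]),
               c(2.5, 4, 7.5, sqrt(1.25)), tolerance = 1e-12)
  expect_equal(unname(s[1, "skewness"]), 0, tolerance = 1e-12)
  # all-zero input: all statistics zero under the stated conventions
  expect_true(all(band_statistics(matrix(0, 128, 5)) == 0))
})

test_that("fusion applies the printed integer weights and is linear", {
  ones <- matrix(1, 128, 6)
  expect_equal(fuse_dwt(ones, ones, ones), rep(7, 768))
  expect_equal(fuse_curvelet(ones, ones, ones, ones), rep(8, 768))
  expect_equal(fuse_curvelet(0 * ones, 0 * ones, 0 * ones, 0 * ones),
               rep(0, 768))
  set.seed(45)
  A <- matrix(rnorm(768), 128, 6); B <- matrix(rnorm(768), 128, 6)
  C <- matrix(rnorm(768), 128, 6)
  expect_equal(fuse_dwt(2 * A, 2 * B, 2 * C), 2 * fuse_dwt(A, B, C),
               tolerance = 1e-12)
  expect_error(fuse_dwt(ones, ones, matrix(1, 64, 6)), "128 x 6")
  # the HH band enters only through an explicit nonzero weight
  expect_equal(fuse_dwt(A, B, C, hh = 100 * A, hh_weight = 0),
               fuse_dwt(A, B, C))
  expect_equal(fuse_dwt(A, B, C, hh = A, hh_weight = 1),
               fuse_dwt(A, B, C) + as.vector(t(A)), tolerance = 1e-12)
})

test_that("reshape order keeps the six statistics of a dimension contiguous", {
  m <- matrix(0, 128, 6)
  m[1, ] <- 1:6
  m[2, ] <- 11:16
  v <- fuse_dwt(m, 0 * m, 0 * m) / 3
  expect_equal(v[1:12], c(1:6, 11:16))
})

test_that("pad_features wraps 768 features into a 784 = 28^2 vector", {
  v <- seq_len(768) / 768
  p <- pad_features(v)
  expect_length(p, 784)
  expect_true(all(p[1:8] == 0))
  expect_true(all(p[777:784] == 0))
  expect_equal(p[9:776], v)
  expect_equal(sum(p), sum(v))
  expect_error(pad_features(numeric(767)), "768")
})

test_that("build_data_matrix stacks augmented rows with labels and groups", {
  set.seed(46)
  patches <- generate_dataset(2, tiny_phantom_cfg(seed = 9))
  M <- build_data_matrix(patches, method = "dwt",
                         dsift_par = dsift_params(step = 8, bin_radius = 3))
  expect_identical(dim(M), c(48L, 785L))          # 6 patches x 8 variants
  expect_equal(as.vector(table(attr(M, "group"))), rep(8, 6))
  labs <- vapply(patches, `[[`, integer(1), "label")
  expect_equal(M[, 785], rep(labs, each = 8))
  # single patch, no augmentation
  M1 <- build_data_matrix(patches[1], method = "dwt",
                          augment_patches = FALSE,
                          dsift_par = dsift_params(step = 8, bin_radius = 3))
  expect_identical(dim(M1), c(1L, 785L))
  # deterministic end to end
  M2 <- build_data_matrix(patches[1], method = "dwt",
                          augment_patches = FALSE,
                          dsift_par = dsift_params(step = 8, bin_radius = 3))
  expect_identical(M1, M2)
})
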