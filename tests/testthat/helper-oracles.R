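# Independent brute-force oracles used across the suite. These are
# deliberately naive re-implementations (direct sums, loops,
# enumeration) kept separate from the package's vectorized code paths.

# plain adaptive histogram equalization (no clipping) with the same
# block geometry and bilinear tile blending: loop-based, per pixel
ahe_oracle <- function(px, block_size = 8L, n_bins = 256L) {
  nr <- nrow(px); nc <- ncol(px)
  g <- pmin(floor(px * n_bins), n_bins - 1L)
  nty <- ceiling(nr / block_size); ntx <- ceiling(nc / block_size)
  luts <- array(0, c(n_bins, nty, ntx))
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    rows <- ((ty - 1) * block_size + 1):min(ty * block_size, nr)
    cols <- ((tx - 1) * block_size + 1):min(tx * block_size, nc)
    h <- tabulate(g[rows, cols] + 1L, nbins = n_bins)
    luts[, ty, tx] <- cumsum(h) / length(g[rows, cols])
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    tyf <- (i - 0.5) / block_size - 0.5
    txf <- (j - 0.5) / block_size - 0.5
    i0 <- min(max(floor(tyf), 0), nty - 1); i1 <- min(i0 + 1, nty - 1)
    j0 <- min(max(floor(txf), 0), ntx - 1); j1 <- min(j0 + 1, ntx - 1)
    fy <- min(max(tyf - i0, 0), 1); fx <- min(max(txf - j0, 0), 1)
    lv <- g[i, j] + 1L
    out[i, j] <-
      luts[lv, i0 + 1, j0 + 1] * (1 - fy) * (1 - fx) +
      luts[lv, i0 + 1, j1 + 1] * (1 - fy) * fx +
      luts[lv, i1 + 1, j0 + 1] * fy * (1 - fx) +
      luts[lv, i1 + 1, j1 + 1] * fy * fx
  }
  out
}

# direct moment sums for the six band statistics, one descriptor
# dimension at a time
stats_oracle <- function(d) {
  K <- ncol(d)
  out <- matrix(0, nrow(d), 6)
  colnames(out) <- c("kurtosis", "mean", "skewness", "energy",
                     "maximum", "sd")
  for (r in seq_len(nrow(d))) {
    v <- d[r, ]
    mu <- sum(v) / K
    m2 <- sum((v - mu)^2) / K
    m3 <- sum((v - mu)^3) / K
    m4 <- sum((v - mu)^4) / K
    out[r, ] <- c(if (m2 > 0) m4 / m2^2 else 0,
                  mu,
                  if (m2 > 0) m3 / m2^1.5 else 0,
                  sum(v^2) / K,
                  max(v),
                  sqrt(m2))
  }
  out
}

# AUC by exhaustive concordant-pair counting (ties count 1/2)
auc_pairs_oracle <- function(pos, score) {
  ip <- which(pos); ineg <- which(!pos)
  tot <- 0
  for (i in ip) for (j in ineg)
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  tot / (length(ip) * length(ineg))
}

# brute-force metric recount from raw label vectors
metrics_oracle <- function(truth, pred, cl) {
  tp <- sum(truth == cl & pred == cl)
  fp <- sum(truth != cl & pred == cl)
  fn <- sum(truth == cl & pred != cl)
  tn <- sum(truth != cl & pred != cl)
  den <- function(x) if (x == 0) NA else x
  mden <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    ppv = if (tp + fp == 0) 0 else tp / (tp + fp),
    npv = if (tn + fn == 0) 0 else tn / (tn + fn),
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    mcc = if (mden == 0) 0 else (tp * tn - fp * fn) / mden)
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1]

# small, quick phantom configuration shared by several tests
tiny_phantom_cfg <- function(seed = 101L)
  phantom_config(patch_size = 64L, mass_radius_range = c(8, 12),
                 seed = seed)
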