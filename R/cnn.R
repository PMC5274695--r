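# Small convolutional network trained by SGD with momentum.
#
# Architecture (valid convolutions, no padding), default configuration:
#   28x28 input -> conv 16@7x7 -> act -> maxpool 2x2  (22 -> 11)
#               -> conv 16@5x5 -> act -> maxpool 2x2  ( 7 ->  3)
#               -> flatten -> fully connected (128) -> act -> dropout
#               -> linear (3) -> softmax
# Convolutions run as im2col matrix products; pooling and its backward
# pass use precomputed quadrant index vectors. All shapes are derived
# from the configuration so a tiny configuration can be gradient-checked.

#' CNN configuration
#'
#' @param input_grid input side length; feature vectors of length
#'   `input_grid^2` are reshaped column-major to the input grid
#'   (default 28, matching the 784 padded features).
#' @param conv1_kernels,conv1_size first convolution: kernel count and
#'   square kernel size (defaults 16 and 7).
#' @param conv2_kernels,conv2_size second convolution (defaults 16, 5).
#' @param activation `"tanh"` (default) or `"sigmoid"`; with heavy
#'   dropout the saturating, non-zero-centred sigmoid trains poorly in
#'   a network this small, so tanh is the default.
#' @param dropout dropout fraction on the fully connected activations
#'   during training, in `[0, 1)` (default 0.55).
#' @param fc_width fully connected layer width (default 128).
#' @param n_classes number of classes (3).
#' @param epochs,learning_rate,batch_size,momentum SGD settings.
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_grid = 28L, conv1_kernels = 16L,
                       conv1_size = 7L, conv2_kernels = 16L,
                       conv2_size = 5L, activation = c("tanh", "sigmoid"),
                       dropout = 0.55, fc_width = 128L, n_classes = 3L,
                       epochs = 30L, learning_rate = 0.01,
                       batch_size = 32L, momentum = 0.9, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(dropout >= 0, dropout < 1, n_classes >= 2,
            conv1_size < input_grid)
  g1 <- input_grid - conv1_size + 1L
  p1 <- g1 %/% 2L
  stopifnot(conv2_size < p1)
  g2 <- p1 - conv2_size + 1L
  p2 <- g2 %/% 2L
  stopifnot(p2 >= 1L)
  structure(list(input_grid = as.integer(input_grid),
                 conv1_kernels = as.integer(conv1_kernels),
                 conv1_size = as.integer(conv1_size),
                 conv2_kernels = as.integer(conv2_kernels),
                 conv2_size = as.integer(conv2_size),
                 activation = activation, dropout = dropout,
                 fc_width = as.integer(fc_width),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 momentum = momentum, seed = as.integer(seed),
                 g1 = g1, p1 = p1, g2 = g2, p2 = p2),
            class = "cnn_config")
}

act_fun <- function(name) switch(name,
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(a) a * (1 - a)),
  tanh = list(f = tanh, df = function(a) 1 - a^2))

# im2col index matrix: rows = output positions (column-major on the
# output grid), cols = (kernel row, kernel col, channel); values are
# linear indices into the (H, W, C) input vector
im2col_idx <- function(H, W, C, k) {
  OH <- H - k + 1L; OW <- W - k + 1L
  pos <- expand.grid(or = seq_len(OH), oc = seq_len(OW))
  off <- expand.grid(kr = 0:(k - 1L), kc = 0:(k - 1L), ch = 0:(C - 1L))
  outer(pos$or + (pos$oc - 1L) * H,
        off$kr + off$kc * H, `+`) +
    matrix(off$ch * H * W, nrow(pos), nrow(off), byrow = TRUE)
}

# 2x2 max-pool quadrant indices on an OH x OW grid (floor semantics:
# trailing odd row/column is dropped)
pool_idx <- function(OH, OW) {
  PH <- OH %/% 2L; PW <- OW %/% 2L
  pr <- rep(seq_len(PH), times = PW); pc <- rep(seq_len(PW), each = PH)
  base <- (2L * pr - 1L) + (2L * pc - 2L) * OH
  list(q = cbind(base, base + 1L, base + OH, base + OH + 1L),
       PH = PH, PW = PW)
}

# forward of one conv layer for a batch:
# X is (in_len x B); returns Z as (P*B x n_k) with row = p + (b-1)*P
conv_forward <- function(X, idx, W, bvec) {
  P <- nrow(idx); B <- ncol(X)
  Xc <- X[as.vector(idx), , drop = FALSE]          # (P*Q) x B
  dim(Xc) <- c(P, ncol(idx), B)
  Xc <- aperm(Xc, c(1, 3, 2))
  dim(Xc) <- c(P * B, ncol(idx))
  Z <- Xc %*% W
  Z <- sweep(Z, 2, bvec, `+`)
  list(Z = Z, Xc = Xc)
}

# max-pool (P*B x C matrix view as (P,B,C) array) -> list(out, argmax)
pool_forward <- function(A, P, B, C, pidx) {
  dim(A) <- c(P, B, C)
  q <- pidx$q
  v1 <- A[q[, 1], , , drop = FALSE]; v2 <- A[q[, 2], , , drop = FALSE]
  v3 <- A[q[, 3], , , drop = FALSE]; v4 <- A[q[, 4], , , drop = FALSE]
  out <- pmax(v1, v2, v3, v4)
  amax <- 1L * (v1 == out)
  amax[v2 == out & amax == 0] <- 2L
  amax[v3 == out & amax == 0] <- 3L
  amax[v4 == out & amax == 0] <- 4L
  list(out = out, argmax = amax)
}

pool_backward <- function(dpool, argmax, P, B, C, pidx) {
  dA <- array(0, c(P, B, C))
  q <- pidx$q
  for (k in 1:4) {
    contrib <- dpool * (argmax == k)
    dA[q[, k], , ] <- dA[q[, k], , , drop = FALSE] + contrib
  }
  dA
}

init_weights <- function(cfg) {
  u <- function(nin, nout, n) {
    s <- sqrt(6 / (nin + nout))
    stats::runif(n, -s, s)
  }
  k1 <- cfg$conv1_size^2
  k2 <- cfg$conv2_size^2 * cfg$conv1_kernels
  flat <- cfg$p2^2 * cfg$conv2_kernels
  list(
    W1 = matrix(u(k1, cfg$conv1_kernels, k1 * cfg$conv1_kernels),
                k1, cfg$conv1_kernels),
    b1 = numeric(cfg$conv1_kernels),
    W2 = matrix(u(k2, cfg$conv2_kernels, k2 * cfg$conv2_kernels),
                k2, cfg$conv2_kernels),
    b2 = numeric(cfg$conv2_kernels),
    W3 = matrix(u(flat, cfg$fc_width, flat * cfg$fc_width),
                flat, cfg$fc_width),
    b3 = numeric(cfg$fc_width),
    W4 = matrix(u(cfg$fc_width, cfg$n_classes,
                  cfg$fc_width * cfg$n_classes),
                cfg$fc_width, cfg$n_classes),
    b4 = numeric(cfg$n_classes))
}

cnn_geometry <- function(cfg) {
  list(idx1 = im2col_idx(cfg$input_grid, cfg$input_grid, 1L,
                         cfg$conv1_size),
       pool1 = pool_idx(cfg$g1, cfg$g1),
       idx2 = im2col_idx(cfg$p1, cfg$p1, cfg$conv1_kernels,
                         cfg$conv2_size),
       pool2 = pool_idx(cfg$g2, cfg$g2))
}

# full forward pass; X is (features x B) already standardized.
# Returns softmax probabilities plus every intermediate needed by
# backprop; drop_mask (fc_width x B) is NULL at inference.
cnn_forward_pass <- function(wts, cfg, geo, X, drop_mask = NULL) {
  B <- ncol(X)
  af <- act_fun(cfg$activation)
  c1 <- conv_forward(X, geo$idx1, wts$W1, wts$b1)
  A1 <- af$f(c1$Z)                                   # (g1^2*B) x k1
  pl1 <- pool_forward(A1, cfg$g1^2, B, cfg$conv1_kernels, geo$pool1)
  X2 <- aperm(pl1$out, c(1, 3, 2))                   # (p1^2, k1, B)
  dim(X2) <- c(cfg$p1^2 * cfg$conv1_kernels, B)
  c2 <- conv_forward(X2, geo$idx2, wts$W2, wts$b2)
  A2 <- af$f(c2$Z)
  pl2 <- pool_forward(A2, cfg$g2^2, B, cfg$conv2_kernels, geo$pool2)
  Xf <- aperm(pl2$out, c(1, 3, 2))
  dim(Xf) <- c(cfg$p2^2 * cfg$conv2_kernels, B)
  Z3 <- t(wts$W3) %*% Xf + wts$b3                    # fc_width x B
  H <- af$f(Z3)
  Hd <- if (is.null(drop_mask)) H else H * drop_mask
  logits <- t(wts$W4) %*% Hd + wts$b4                # n_classes x B
  lmax <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, lmax, `-`))
  probs <- sweep(e, 2, colSums(e), `/`)
  list(probs = probs, H = H, Hd = Hd, Z3 = Z3, Xf = Xf,
       c1 = c1, A1 = A1, pl1 = pl1, X2 = X2, c2 = c2, A2 = A2,
       pl2 = pl2, B = B)
}

# mean cross-entropy gradient for a batch; y is 1..n_classes
cnn_backward_pass <- function(wts, cfg, geo, fw, y, drop_mask = NULL) {
  B <- fw$B
  af <- act_fun(cfg$activation)
  dlogit <- fw$probs
  dlogit[cbind(y, seq_len(B))] <- dlogit[cbind(y, seq_len(B))] - 1
  dlogit <- dlogit / B
  gW4 <- fw$Hd %*% t(dlogit)
  gb4 <- rowSums(dlogit)
  dH <- wts$W4 %*% dlogit
  if (!is.null(drop_mask)) dH <- dH * drop_mask
  dZ3 <- dH * af$df(fw$H)
  gW3 <- fw$Xf %*% t(dZ3)
  gb3 <- rowSums(dZ3)
  dXf <- wts$W3 %*% dZ3                              # flat x B
  dim(dXf) <- c(cfg$p2^2, cfg$conv2_kernels, B)
  dpool2 <- aperm(dXf, c(1, 3, 2))
  dA2 <- pool_backward(dpool2, fw$pl2$argmax, cfg$g2^2, B,
                       cfg$conv2_kernels, geo$pool2)
  dim(dA2) <- c(cfg$g2^2 * B, cfg$conv2_kernels)
  dZ2 <- dA2 * af$df(fw$A2)
  gW2 <- t(fw$c2$Xc) %*% dZ2
  gb2 <- colSums(dZ2)
  # scatter conv2 input gradient back through the im2col map
  dXc2 <- dZ2 %*% t(wts$W2)                          # (P2*B) x Q2
  P2 <- cfg$g2^2
  dim(dXc2) <- c(P2, B, ncol(geo$idx2))
  dXc2 <- aperm(dXc2, c(1, 3, 2))
  dim(dXc2) <- c(P2 * ncol(geo$idx2), B)
  tgt <- as.vector(geo$idx2)
  agg <- rowsum(dXc2, tgt)
  dX2 <- matrix(0, cfg$p1^2 * cfg$conv1_kernels, B)
  dX2[as.integer(rownames(agg)), ] <- agg
  dim(dX2) <- c(cfg$p1^2, cfg$conv1_kernels, B)
  dpool1 <- aperm(dX2, c(1, 3, 2))
  dA1 <- pool_backward(dpool1, fw$pl1$argmax, cfg$g1^2, B,
                       cfg$conv1_kernels, geo$pool1)
  dim(dA1) <- c(cfg$g1^2 * B, cfg$conv1_kernels)
  dZ1 <- dA1 * af$df(fw$A1)
  gW1 <- t(fw$c1$Xc) %*% dZ1
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

cnn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_len(ncol(probs)))], 1e-12)))
}

# standardize rows of an N x F matrix with a fitted scaler -> N x F
std_features <- function(x, st) t((t(x) - st$mu) / st$sd)

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

#' Train the small CNN
#'
#' Minimizes softmax cross-entropy by mini-batch SGD with momentum.
#' Features are standardized per column (z-score from the training set;
#' the scaler is stored in the model and re-applied at inference).
#' Dropout is active only during training. Bit-reproducible given
#' `cfg$seed`.
#'
#' @param cfg a [cnn_config()].
#' @param x numeric matrix N x `input_grid^2` of features.
#' @param y integer labels in `0..n_classes-1`.
#' @param x_val,y_val optional validation set logged per epoch.
#' @return a `trained_cnn`: weights, scaler, config and a `history`
#'   data.frame (epoch, train_acc, val_acc, train_err, val_err in
#'   percent; error = 100 - accuracy).
#' @export
cnn_train <- function(cfg, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(is.matrix(x), ncol(x) == cfg$input_grid^2,
            nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < cfg$n_classes)
    stop("training data must contain every class; found only ",
         paste(classes, collapse = ", "))
  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(restore_seed(old), add = TRUE)
  st <- standardize_fit(x)
  Xs <- std_features(x, st)                          # N x F
  XT <- t(Xs)                                        # F x N
  yi <- as.integer(y) + 1L
  geo <- cnn_geometry(cfg)
  wts <- init_weights(cfg)
  vel <- lapply(wts, function(w) w * 0)
  n <- nrow(x)
  hist_rows <- vector("list", cfg$epochs)
  Xval <- if (!is.null(x_val)) std_features(x_val, st) else NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1, n)]
      Xb <- XT[, bi, drop = FALSE]
      drop_mask <- if (cfg$dropout > 0)
        matrix(stats::rbinom(cfg$fc_width * length(bi), 1,
                             1 - cfg$dropout) / (1 - cfg$dropout),
               cfg$fc_width, length(bi))
      else NULL
      fw <- cnn_forward_pass(wts, cfg, geo, Xb, drop_mask)
      gr <- cnn_backward_pass(wts, cfg, geo, fw, yi[bi], drop_mask)
      for (nm in names(wts)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * gr[[nm]]
        wts[[nm]] <- wts[[nm]] + vel[[nm]]
      }
    }
    tr_pred <- cnn_predict_stdzd(wts, cfg, geo, XT)
    tr_acc <- 100 * mean(tr_pred == yi)
    if (!is.null(Xval)) {
      va_pred <- cnn_predict_stdzd(wts, cfg, geo, t(Xval))
      va_acc <- 100 * mean(va_pred == as.integer(y_val) + 1L)
    } else va_acc <- NA_real_
    hist_rows[[ep]] <- data.frame(epoch = ep, train_acc = tr_acc,
                                  val_acc = va_acc,
                                  train_err = 100 - tr_acc,
                                  val_err = 100 - va_acc)
  }
  structure(list(weights = wts, cfg = cfg, scaler = st,
                 history = do.call(rbind, hist_rows)),
            class = "trained_cnn")
}

# predict class indices (1-based) from standardized (F x N) features,
# processed in chunks to bound memory
cnn_predict_stdzd <- function(wts, cfg, geo, XT, chunk = 256L) {
  n <- ncol(XT)
  out <- integer(n)
  for (s in seq(1, n, by = chunk)) {
    i <- s:min(s + chunk - 1, n)
    fw <- cnn_forward_pass(wts, cfg, geo, XT[, i, drop = FALSE])
    out[i] <- max.col(t(fw$probs), ties.method = "first")
  }
  out
}

#' Class probabilities from a trained CNN
#'
#' @param model a `trained_cnn`.
#' @param x numeric matrix N x `input_grid^2`.
#' @return N x `n_classes` matrix of softmax probabilities; rows sum
#'   to 1.
#' @export
cnn_forward <- function(model, x) {
  stopifnot(inherits(model, "trained_cnn"), is.matrix(x))
  cfg <- model$cfg
  if (ncol(x) != cfg$input_grid^2)
    stop("expected ", cfg$input_grid^2, " features per row, got ", ncol(x))
  XT <- t(std_features(x, model$scaler))
  geo <- cnn_geometry(cfg)
  n <- ncol(XT)
  out <- matrix(0, n, cfg$n_classes)
  for (s in seq(1, n, by = 256L)) {
    i <- s:min(s + 255L, n)
    fw <- cnn_forward_pass(model$weights, cfg, geo, XT[, i, drop = FALSE])
    out[i, ] <- t(fw$probs)
  }
  out
}

#' Predicted labels from a trained CNN
#' @param model a `trained_cnn`.
#' @param x feature matrix.
#' @return integer labels in `0..n_classes-1`.
#' @export
cnn_predict <- function(model, x) {
  max.col(cnn_forward(model, x), ties.method = "first") - 1L
}

#' Penultimate-layer activations
#'
#' Activations of the fully connected layer (before the classification
#' layer, dropout off): the representation consumed by the SVM head.
#'
#' @param model a `trained_cnn`.
#' @param x feature matrix N x `input_grid^2`.
#' @return N x `fc_width` matrix.
#' @export
penultimate_features <- function(model, x) {
  stopifnot(inherits(model, "trained_cnn"), is.matrix(x))
  cfg <- model$cfg
  XT <- t(std_features(x, model$scaler))
  geo <- cnn_geometry(cfg)
  n <- ncol(XT)
  out <- matrix(0, n, cfg$fc_width)
  for (s in seq(1, n, by = 256L)) {
    i <- s:min(s + 255L, n)
    fw <- cnn_forward_pass(model$weights, cfg, geo, XT[, i, drop = FALSE])
    out[i, ] <- t(fw$H)
  }
  out
}
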