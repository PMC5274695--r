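#' @keywords internal
clamp01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' Bilinear resampling of a matrix
#'
#' Resamples a real-valued image matrix to a target size using bilinear
#' interpolation on a pixel-center grid. Used to bring curvelet scale
#' bands to the common subband geometry shared with the wavelet branch.
#'
#' @param img numeric matrix.
#' @param out_rows,out_cols target dimensions.
#' @return numeric matrix of size `out_rows` x `out_cols`.
#' @keywords internal
resize_bilinear <- function(img, out_rows, out_cols) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr == out_rows && nc == out_cols) return(img)
  # map output pixel centers onto input pixel centers
  ry <- (seq_len(out_rows) - 0.5) * nr / out_rows + 0.5
  rx <- (seq_len(out_cols) - 0.5) * nc / out_cols + 0.5
  y0 <- pmin(pmax(floor(ry), 1), nr); y1 <- pmin(y0 + 1, nr)
  x0 <- pmin(pmax(floor(rx), 1), nc); x1 <- pmin(x0 + 1, nc)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_rows, out_cols)
  wx <- matrix(fx, out_rows, out_cols, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx +
    c_ * wy * (1 - wx) + d * wy * wx
}

#' Gaussian smoothing by FFT (periodic boundary)
#' @keywords internal
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- nrow(img); m <- ncol(img)
  fy <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  # transfer function of a sampled Gaussian kernel
  hy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  hx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  H <- outer(hy, hx)
  Re(fft(fft(img) * H, inverse = TRUE)) / (n * m)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
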