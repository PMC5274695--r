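#' Orthonormal Daubechies scaling filters
#'
#' Returns the low-pass (scaling) filter of the requested orthonormal
#' wavelet; the high-pass filter is derived by the alternating-flip
#' quadrature-mirror relation `g[k] = (-1)^k h[L-1-k]`.
#'
#' @param wavelet one of `"haar"`, `"db2"`, `"db4"`, `"db8"`.
#' @return list with numeric vectors `h` (low-pass) and `g` (high-pass).
#' @export
wavelet_filters <- function(wavelet = "db4") {
  lo <- switch(wavelet,
    haar = c(0.70710678118654757, 0.70710678118654757),
    db2 = c(0.48296291314453416, 0.83651630373780794,
            0.22414386804201339, -0.12940952255126037),
    db4 = c(0.23037781330889651, 0.71484657055291567,
            0.63088076792985892, -0.027983769416859854,
            -0.18703481171909309, 0.030841381835560764,
            0.032883011666885197, -0.010597401785069032),
    db8 = c(0.054415842243104008, 0.31287159091429995,
            0.67563073629728976, 0.58535468365420673,
            -0.015829105256349306, -0.28401554296154691,
            0.00047248457391328279, 0.12874742662047847,
            -0.017369301001807547, -0.044088253930794755,
            0.013981027917398282, 0.0087460940474057766,
            -0.0048703529934515741, -0.00039174037337694705,
            0.00067544940645056933, -0.00011747678412476953),
    stop("unknown wavelet name: ", wavelet))
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(h = lo, g = hi)
}

# orthogonal one-level analysis operator for a length-n periodic signal:
# rows 1..n/2 are the shifted low-pass filter, rows n/2+1..n the shifted
# high-pass filter; W %*% x gives c(approx, detail) and W is orthogonal
dwt_operator <- function(n, filt) {
  stopifnot(n %% 2 == 0, length(filt$h) <= n)
  half <- n / 2
  W <- matrix(0, n, n)
  L <- length(filt$h)
  for (m in seq_len(half)) {
    idx <- ((2 * (m - 1) + seq_len(L) - 1) %% n) + 1
    for (k in seq_len(L)) {
      W[m, idx[k]] <- W[m, idx[k]] + filt$h[k]
      W[half + m, idx[k]] <- W[half + m, idx[k]] + filt$g[k]
    }
  }
  W
}

new_subband_set <- function(branch, bands, source_size) {
  stopifnot(branch %in% c("dwt", "curvelet"), length(bands) == 4)
  structure(list(branch = branch, bands = bands,
                 source_size = source_size),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set %s: %s; band size %dx%d; source %d>\n",
              x$branch, paste(names(x$bands), collapse = " "),
              nrow(x$bands[[1]]), ncol(x$bands[[1]]), x$source_size))
  invisible(x)
}

#' One-level 2-D discrete wavelet transform
#'
#' Separable one-level DWT with periodic boundary handling: rows and
#' columns are filtered by the orthonormal low/high-pass pair and
#' dyadically downsampled, yielding the four subbands LL (approximation),
#' LH (vertical detail), HL (horizontal detail) and HH (diagonal detail),
#' each half the linear size of the input. With an orthonormal filter
#' the transform conserves energy exactly and inverts exactly.
#'
#' @param p a `mammo_patch` or numeric matrix with even dimensions.
#' @param wavelet wavelet name, see [wavelet_filters()].
#' @return a `subband_set` with bands `LL`, `LH`, `HL`, `HH`.
#' @export
dwt2 <- function(p, wavelet = "db4") {
  x <- if (inherits(p, "mammo_patch")) p$pixels else p
  stopifnot(is.matrix(x))
  if (nrow(x) %% 2 != 0 || ncol(x) %% 2 != 0)
    stop("dwt2() requires even image dimensions")
  filt <- wavelet_filters(wavelet)
  Wr <- dwt_operator(nrow(x), filt)
  Wc <- if (ncol(x) == nrow(x)) Wr else dwt_operator(ncol(x), filt)
  A <- Wr %*% x %*% t(Wc)
  hr <- nrow(x) / 2; hc <- ncol(x) / 2
  bands <- list(
    LL = A[1:hr, 1:hc],
    LH = A[1:hr, (hc + 1):(2 * hc)],
    HL = A[(hr + 1):(2 * hr), 1:hc],
    HH = A[(hr + 1):(2 * hr), (hc + 1):(2 * hc)])
  new_subband_set("dwt", bands, nrow(x))
}

#' Inverse one-level 2-D DWT
#'
#' Exact inverse of [dwt2()] for orthonormal filters.
#'
#' @param sb a `subband_set` from [dwt2()].
#' @param wavelet wavelet name used in the forward transform.
#' @return reconstructed numeric matrix.
#' @export
idwt2 <- function(sb, wavelet = "db4") {
  stopifnot(inherits(sb, "subband_set"), sb$branch == "dwt")
  b <- sb$bands
  A <- rbind(cbind(b$LL, b$LH), cbind(b$HL, b$HH))
  filt <- wavelet_filters(wavelet)
  Wr <- dwt_operator(nrow(A), filt)
  Wc <- if (ncol(A) == nrow(A)) Wr else dwt_operator(ncol(A), filt)
  t(Wr) %*% A %*% Wc
}
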