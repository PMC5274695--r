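#' Dense SIFT parameters
#'
#' @param step grid spacing between keypoints in pixels (default 4).
#' @param bin_radius side of one spatial bin in pixels (default 5); the
#'   descriptor support is `4 * bin_radius` pixels square (4x4 spatial
#'   bins x 8 orientation bins = 128 dimensions).
#' @return list of class `dsift_params`.
#' @export
dsift_params <- function(step = 4L, bin_radius = 5L) {
  stopifnot(step >= 1, bin_radius >= 1)
  structure(list(step = as.integer(step),
                 bin_radius = as.integer(bin_radius)),
            class = "dsift_params")
}

.dsift_cache <- new.env(parent = emptyenv())

# geometry shared by every keypoint of a band; the keypoint grid is
# centred so that it is symmetric under 180-degree rotation whenever
# the leftover margin splits evenly
dsift_geometry <- function(nr, nc, params) {
  key <- paste(nr, nc, params$step, params$bin_radius, sep = "_")
  if (!is.null(.dsift_cache[[key]])) return(.dsift_cache[[key]])
  br <- params$bin_radius
  support <- 4L * br
  if (nr < support || nc < support)
    stop("band too small for dense SIFT: needs at least ",
         support, " pixels per side")
  npos <- function(n) (n - support) %/% params$step + 1L
  offs <- function(n, k) (n - support - (k - 1L) * params$step) %/% 2L
  ky <- npos(nr); kx <- npos(nc)
  y0 <- offs(nr, ky) + seq.int(0L, by = params$step, length.out = ky)
  x0 <- offs(nc, kx) + seq.int(0L, by = params$step, length.out = kx)
  # Gaussian weight per spatial bin, evaluated at the bin centre
  # (flat within a bin), sigma = half the descriptor support
  ctr <- (support - 1) / 2
  bc <- (0:3) * br + (br - 1) / 2
  gw <- outer(exp(-(bc - ctr)^2 / (2 * (support / 2)^2)),
              exp(-(bc - ctr)^2 / (2 * (support / 2)^2)))
  out <- list(y0 = y0, x0 = x0, support = support, br = br,
              gw = gw, nr = nr, nc = nc)
  .dsift_cache[[key]] <- out
  out
}

# integral image with a leading zero row/column, so the sum of
# img[r1:r2, c1:c2] is S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1]
integral_image <- function(img) {
  S <- apply(img, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  rbind(0, cbind(0, S))
}

#' Dense SIFT descriptors on a fixed keypoint grid
#'
#' Computes 128-dimensional gradient-orientation histogram descriptors
#' (4x4 spatial bins x 8 orientation bins) at a fixed scale on a
#' regular, centred grid of keypoints. Gradients are central
#' differences with replicated edges; each pixel's magnitude is split
#' linearly between the two nearest orientation bins, spatial pooling
#' is flat within each bin with a Gaussian weight per bin centre, and
#' bin sums are evaluated as integral-image box sums so the cost is
#' independent of the keypoint count. Descriptors are L2-normalized
#' with the standard 0.2 clamp-and-renormalize; the zero vector
#' normalizes to zero. Fully deterministic.
#'
#' @param band numeric matrix (a subband image), at least
#'   `4 * bin_radius` pixels on each side.
#' @param params a [dsift_params()].
#' @return a `descriptor_matrix`: 128 x K numeric matrix (K keypoints,
#'   all entries >= 0) with attribute `keypoints` (K x 2 grid
#'   positions, 1-based window corners).
#' @export
dsift <- function(band, params = dsift_params()) {
  stopifnot(is.matrix(band))
  geo <- dsift_geometry(nrow(band), ncol(band), params)
  nr <- nrow(band); nc <- ncol(band)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  gy <- (band[ip, ] - band[im, ]) / 2
  gx <- (band[, jp] - band[, jm]) / 2
  mag <- sqrt(gy^2 + gx^2)
  obin_f <- (atan2(gy, gx) %% (2 * pi)) / (2 * pi / 8)
  b0 <- floor(obin_f) %% 8
  fo <- obin_f - floor(obin_f)
  # integral image per soft-binned orientation channel
  S <- vector("list", 8L)
  w0 <- mag * (1 - fo); w1 <- mag * fo
  for (o in 0:7) {
    ch <- w0 * (b0 == o) + w1 * ((b0 + 1) %% 8 == o)
    S[[o + 1L]] <- integral_image(ch)
  }
  K <- length(geo$y0) * length(geo$x0)
  kyy <- rep(geo$y0, times = length(geo$x0))     # 0-based corner rows
  kxx <- rep(geo$x0, each = length(geo$y0))
  br <- geo$br
  desc <- matrix(0, 128L, K)
  for (sy in 0:3) for (sx in 0:3) {
    r1 <- kyy + sy * br; r2 <- r1 + br            # [r1+1, r2] rows
    c1 <- kxx + sx * br; c2 <- c1 + br
    w <- geo$gw[sy + 1L, sx + 1L]
    i11 <- r1 + c1 * (nr + 1L) + 1L               # (r1+1, c1+1) of S
    i12 <- r1 + c2 * (nr + 1L) + 1L
    i21 <- r2 + c1 * (nr + 1L) + 1L
    i22 <- r2 + c2 * (nr + 1L) + 1L
    s <- (sy + 4L * sx) * 8L
    for (o in 1:8) {
      So <- S[[o]]
      desc[s + o, ] <- w * (So[i22] - So[i12] - So[i21] + So[i11])
    }
  }
  desc[desc < 0] <- 0            # guard: box-sum cancellation residue
  # L2 normalize, clamp at 0.2, renormalize; zero vectors stay zero
  nrm <- sqrt(colSums(desc^2))
  nz <- nrm > 0
  desc[, nz] <- sweep(desc[, nz, drop = FALSE], 2, nrm[nz], `/`)
  desc <- pmin(desc, 0.2)
  dim(desc) <- c(128L, K)
  nrm2 <- sqrt(colSums(desc^2))
  nz <- nrm2 > 0
  desc[, nz] <- sweep(desc[, nz, drop = FALSE], 2, nrm2[nz], `/`)
  structure(desc, keypoints = cbind(y = kyy + 1L, x = kxx + 1L),
            class = c("descriptor_matrix", class(desc)))
}
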