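#' Eight-fold geometric augmentation
#'
#' Expands one square patch into its eight dihedral variants: identity,
#' rotations by 90/180/270 degrees, horizontal flip, and the flip
#' composed with each rotation. Labels are copied. This is the standard
#' label-preserving augmentation for mammogram patches, where lesion
#' class does not depend on orientation.
#'
#' @param p a `mammo_patch` (or plain square matrix).
#' @return list of 8 patches in the fixed order
#'   `identity, rot90, rot180, rot270, flip, flip.rot90, flip.rot180,
#'   flip.rot270`.
#' @export
augment <- function(p) {
  px <- if (inherits(p, "mammo_patch")) p$pixels else p
  if (!is.matrix(px) || nrow(px) != ncol(px))
    stop("augment() requires a square patch")
  rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  fliplr <- function(m) m[, ncol(m):1, drop = FALSE]
  variants <- list(
    identity   = px,
    rot90      = rot90cw(px),
    rot180     = rot90cw(rot90cw(px)),
    rot270     = rot90cw(rot90cw(rot90cw(px))),
    flip       = fliplr(px),
    flip.rot90 = fliplr(rot90cw(px)),
    flip.rot180 = fliplr(rot90cw(rot90cw(px))),
    flip.rot270 = fliplr(rot90cw(rot90cw(rot90cw(px)))))
  if (inherits(p, "mammo_patch")) {
    lapply(variants, function(m) {
      q <- new_patch(m, p$label)
      q
    })
  } else variants
}

#' CLAHE parameters
#'
#' @param block_size side of the square non-overlapping blocks in
#'   pixels. The default 16 divides the standard 128-pixel patch into
#'   an 8 x 8 grid of tiles — the conventional tile-count
#'   parameterization of adaptive equalization toolboxes, under which
#'   the clip limit actually engages; set `block_size = 8` for literal
#'   8x8-pixel blocks (256 tiny tiles), which behaves as nearly
#'   unclipped local equalization.
#' @param clip_limit histogram clip limit as a fraction of the block
#'   pixel count (default 0.001); the per-bin clip is
#'   `max(1, floor(clip_limit * m))` counts for a block of `m` pixels.
#' @param n_bins histogram bin count (default 256, matching 8-bit data).
#' @return list of class `clahe_params`.
#' @export
clahe_params <- function(block_size = 16L, clip_limit = 0.001,
                         n_bins = 256L) {
  stopifnot(block_size >= 1, clip_limit > 0, clip_limit <= 1, n_bins >= 2)
  structure(list(block_size = as.integer(block_size),
                 clip_limit = clip_limit,
                 n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

# clip a block histogram at `clip` counts and redistribute the excess
# uniformly over all bins (single pass, no re-clipping); total mass is
# conserved exactly
clip_redistribute <- function(h, clip) {
  excess <- sum(pmax(h - clip, 0))
  pmin(h, clip) + excess / length(h)
}

# cumulative transformation (equalization mapping) of one block:
# A_t = sum_{i<=t} p_t(A_i), values in [0,1], nondecreasing
block_mapping <- function(h, m) cumsum(h) / m

#' Contrast-limited adaptive histogram equalization
#'
#' Divides the patch into non-overlapping square blocks, computes each
#' block's gray-level histogram, clips it at a limit proportional to the
#' block pixel count, redistributes the clipped mass uniformly, applies
#' the cumulative (equalization) mapping per block, and blends the
#' per-block mappings with bilinear interpolation between block centers
#' so tile seams are invisible. Edge and corner pixels fall back to
#' 1- or 2-neighbor blends by clamping. Intensities stay in `[0, 1]`.
#'
#' @param p a `mammo_patch` or numeric matrix with values in `[0, 1]`.
#' @param params a [clahe_params()].
#' @return enhanced patch of the same type and size; label preserved.
#' @export
clahe <- function(p, params = clahe_params()) {
  px <- if (inherits(p, "mammo_patch")) p$pixels else p
  stopifnot(is.matrix(px))
  if (min(px) < -1e-9 || max(px) > 1 + 1e-9)
    stop("clahe() expects intensities in [0, 1]")
  bs <- params$block_size
  nb <- params$n_bins
  nr <- nrow(px); nc <- ncol(px)
  if (bs > nr || bs > nc) stop("block larger than image")
  g <- pmin(floor(px * nb), nb - 1L)           # gray levels 0..nb-1
  nty <- ceiling(nr / bs); ntx <- ceiling(nc / bs)
  lut <- array(0, c(nb, nty, ntx))
  for (tx in seq_len(ntx)) {
    cols <- (((tx - 1) * bs + 1):min(tx * bs, nc))
    for (ty in seq_len(nty)) {
      rows <- (((ty - 1) * bs + 1):min(ty * bs, nr))
      blk <- g[rows, cols]
      m <- length(blk)
      h <- tabulate(blk + 1L, nbins = nb)
      clip <- max(1, floor(params$clip_limit * m))
      h <- clip_redistribute(h, clip)
      lut[, ty, tx] <- block_mapping(h, m)
    }
  }
  # bilinear blend between the four surrounding block mappings
  ty_f <- (seq_len(nr) - 0.5) / bs - 0.5       # fractional tile coords
  tx_f <- (seq_len(nc) - 0.5) / bs - 0.5
  i0 <- pmin(pmax(floor(ty_f), 0), nty - 1); i1 <- pmin(i0 + 1, nty - 1)
  j0 <- pmin(pmax(floor(tx_f), 0), ntx - 1); j1 <- pmin(j0 + 1, ntx - 1)
  fy <- pmin(pmax(ty_f - i0, 0), 1); fx <- pmin(pmax(tx_f - j0, 0), 1)
  FY <- matrix(fy, nr, nc); FX <- matrix(fx, nr, nc, byrow = TRUE)
  G1 <- g + 1L
  at <- function(iy, jx) {
    # linear index into lut[nb, nty, ntx] for every pixel
    I <- matrix(iy, nr, nc); J <- matrix(jx, nr, nc, byrow = TRUE)
    matrix(lut[G1 + nb * I + nb * nty * J], nr, nc)
  }
  out <- at(i0, j0) * (1 - FY) * (1 - FX) + at(i0, j1) * (1 - FY) * FX +
    at(i1, j0) * FY * (1 - FX) + at(i1, j1) * FY * FX
  out <- clamp01(out)
  if (inherits(p, "mammo_patch")) {
    q <- p; q$pixels <- out; q
  } else out
}
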