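# Frequency-wedge curvelet frame.
#
# The transform is realized as an undecimated tight frame: smooth radial
# ring windows (Meyer-style cos^2 ramps whose squares telescope) split
# the spectrum into a coarse isotropic scale plus band-pass rings, and
# each detail ring is further split by smooth angular windows whose
# squares partition unity around the circle. Every window U satisfies
# sum_w U_w^2 = 1 on the sampled grid, so analysis (multiply the FFT by
# U_w, inverse-transform) followed by synthesis (re-window and sum) is
# exact to machine precision. Coefficient arrays stay at full grid size,
# which keeps orientations aligned for magnitude aggregation.

.curvelet_cache <- new.env(parent = emptyenv())

# smooth lowpass profile: 1 for r <= a, cos ramp to 0 at b
cos_lowpass <- function(r, a, b) {
  t <- pmin(pmax((r - a) / (b - a), 0), 1)
  cos(pi * t / 2)
}

# build the full set of frequency windows for an n x n grid
curvelet_windows <- function(n, n_scales = 4L, n_orient = 8L) {
  key <- paste(n, n_scales, n_orient, sep = "_")
  if (!is.null(.curvelet_cache[[key]])) return(.curvelet_cache[[key]])
  stopifnot(n_scales >= 2)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  FY <- matrix(f, n, n)
  FX <- matrix(f, n, n, byrow = TRUE)
  r <- sqrt(FY^2 + FX^2)
  th <- atan2(FY, FX)
  # nested lowpass profiles with dyadic cutoffs; finest cutoff 0.25
  cuts <- 0.5 / 2^((n_scales - 1):1)        # e.g. 0.0625 0.125 0.25
  if (min(cuts) * n < 2)
    stop("n_scales too large for image size")
  phi <- lapply(cuts, function(cut) cos_lowpass(r, cut / 2, cut))
  ring2 <- vector("list", n_scales)
  ring2[[1]] <- phi[[1]]^2
  if (n_scales > 2)
    for (j in 2:(n_scales - 1)) ring2[[j]] <- phi[[j]]^2 - phi[[j - 1]]^2
  ring2[[n_scales]] <- 1 - phi[[n_scales - 1]]^2
  # angular windows: cos/sin ramps between wedge centers; squares sum to 1
  ov <- 0.25
  ang2 <- vector("list", n_orient)
  for (k in seq_len(n_orient)) {
    ctr <- 2 * pi * (k - 1) / n_orient
    d <- abs(((th - ctr + pi) %% (2 * pi)) - pi) / (2 * pi / n_orient)
    ang2[[k]] <- cos_lowpass(d, 0.5 - ov, 0.5 + ov)^2
  }
  windows <- list(list(scale = 1L, orient = NA_integer_,
                       U = sqrt(pmax(ring2[[1]], 0))))
  for (j in 2:n_scales) for (k in seq_len(n_orient))
    windows[[length(windows) + 1L]] <-
      list(scale = j, orient = k, U = sqrt(pmax(ring2[[j]] * ang2[[k]], 0)))
  out <- list(windows = windows, n = n, n_scales = n_scales,
              n_orient = n_orient)
  .curvelet_cache[[key]] <- out
  out
}

#' Fast discrete curvelet analysis
#'
#' Decomposes a square patch into curvelet coefficients: the 2-D Fourier
#' transform is multiplied by smooth frequency windows (one isotropic
#' coarse window plus, per detail scale, `n_orient` angular wedges) and
#' inverse-transformed per window. The window squares partition unity,
#' so the frame is tight and [icurvelet()] reconstructs exactly.
#'
#' @param p a `mammo_patch` or square numeric matrix.
#' @param n_scales number of scales (>= 2; default 4, giving the four
#'   spatial-frequency bands F1-F4).
#' @param n_orient angular wedges per detail scale (default 8).
#' @return a `curvelet_frame`: list of coefficient arrays (complex,
#'   full grid size) tagged with scale and orientation.
#' @export
curvelet <- function(p, n_scales = 4L, n_orient = 8L) {
  x <- if (inherits(p, "mammo_patch")) p$pixels else p
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  w <- curvelet_windows(nrow(x), n_scales, n_orient)
  Xh <- stats::fft(x)
  n2 <- length(x)
  coef <- lapply(w$windows, function(win)
    list(scale = win$scale, orient = win$orient,
         C = stats::fft(Xh * win$U, inverse = TRUE) / n2))
  structure(list(coef = coef, n = nrow(x), n_scales = n_scales,
                 n_orient = n_orient),
            class = "curvelet_frame")
}

#' Curvelet synthesis (exact inverse)
#'
#' @param frame a `curvelet_frame` from [curvelet()].
#' @return reconstructed real matrix.
#' @export
icurvelet <- function(frame) {
  stopifnot(inherits(frame, "curvelet_frame"))
  w <- curvelet_windows(frame$n, frame$n_scales, frame$n_orient)
  acc <- matrix(0 + 0i, frame$n, frame$n)
  for (i in seq_along(frame$coef))
    acc <- acc + stats::fft(frame$coef[[i]]$C) * w$windows[[i]]$U
  Re(stats::fft(acc, inverse = TRUE)) / length(acc)
}

#' Per-orientation coefficient energy
#'
#' Sum of squared coefficient magnitudes per (scale, orientation) wedge;
#' useful for checking orientation selectivity.
#'
#' @param frame a `curvelet_frame`.
#' @return data.frame with columns `scale`, `orient`, `energy`.
#' @export
curvelet_energy <- function(frame) {
  do.call(rbind, lapply(frame$coef, function(co)
    data.frame(scale = co$scale, orient = co$orient,
               energy = sum(Mod(co$C)^2))))
}

#' Collapse a curvelet frame to four scale bands F1-F4
#'
#' Per scale, orientation coefficient magnitudes are combined by
#' root-sum-square at aligned positions and the result is resampled to
#' a common band size, giving real-valued band images F1 (coarsest)
#' through F4 (finest) with the same geometry as the wavelet subbands.
#'
#' @param frame a `curvelet_frame` with 4 scales.
#' @param target_size band side length in pixels (default 64).
#' @return a `subband_set` with bands `F1`..`F4`.
#' @export
curvelet_bands <- function(frame, target_size = 64L) {
  stopifnot(inherits(frame, "curvelet_frame"), frame$n_scales >= 4)
  bands <- vector("list", 4L)
  grp <- cut(vapply(frame$coef, `[[`, integer(1), "scale"),
             breaks = c(0.5, 1.5, 2.5, 3.5, Inf), labels = FALSE)
  for (b in 1:4) {
    sel <- which(grp == b)
    acc <- matrix(0, frame$n, frame$n)
    for (i in sel) acc <- acc + Mod(frame$coef[[i]]$C)^2
    bands[[b]] <- resize_bilinear(sqrt(acc), target_size, target_size)
  }
  names(bands) <- paste0("F", 1:4)
  new_subband_set("curvelet", bands, frame$n)
}
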