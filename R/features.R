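#' Six-statistic summary of a descriptor matrix
#'
#' For each of the 128 descriptor dimensions, computes six statistics
#' across the K keypoints, in the fixed column order
#' `kurtosis, mean, skewness, energy, maximum, sd`:
#' kurtosis and skewness are the population (biased) standardized
#' moments, with kurtosis non-excess (a normal sample tends to 3);
#' energy is the mean of squares; sd is the population standard
#' deviation. Rows with zero variance get kurtosis = 0 and skewness = 0
#' by convention, so a constant (e.g. all-zero) descriptor matrix maps
#' to an all-zero summary. All six are K-invariant summaries, so bands
#' whose grids differ in keypoint count remain comparable.
#'
#' @param d a 128 x K `descriptor_matrix` (K >= 2).
#' @return a 128 x 6 `stat_matrix`.
#' @export
band_statistics <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == 128L)
  K <- ncol(d)
  if (K < 2) stop("band_statistics() needs at least 2 keypoints")
  mu <- rowMeans(d)
  ctr <- d - mu
  m2 <- rowMeans(ctr^2)
  m3 <- rowMeans(ctr^3)
  m4 <- rowMeans(ctr^4)
  sdv <- sqrt(m2)
  nzv <- m2 > 0
  skew <- ifelse(nzv, m3 / m2^1.5, 0)
  kurt <- ifelse(nzv, m4 / m2^2, 0)
  out <- cbind(kurtosis = kurt, mean = mu, skewness = skew,
               energy = rowMeans(d^2),
               maximum = apply(d, 1, max), sd = sdv)
  structure(out, class = c("stat_matrix", class(out)))
}

check_stat_shape <- function(...) {
  mats <- list(...)
  for (m in mats)
    if (!is.matrix(m) || !all(dim(m) == c(128L, 6L)))
      stop("statistic matrices must all be 128 x 6")
  invisible(TRUE)
}

#' Weighted subband fusion, wavelet branch
#'
#' Elementwise weighted sum `3*LL + 2*LH + 2*HL` of the subband
#' statistic matrices, flattened row-major (the six statistics of each
#' descriptor dimension stay contiguous) to a length-768 vector. The HH
#' band carries weight `hh_weight` (default 0, i.e. excluded, as the
#' fusion rule prints; set it to include diagonal detail).
#'
#' @param ll,lh,hl 128 x 6 `stat_matrix` inputs.
#' @param hh optional 128 x 6 `stat_matrix`; used only if
#'   `hh_weight != 0`.
#' @param hh_weight weight on the HH band (default 0).
#' @return numeric vector of length 768.
#' @export
fuse_dwt <- function(ll, lh, hl, hh = NULL, hh_weight = 0) {
  check_stat_shape(ll, lh, hl)
  fused <- 3 * ll + 2 * lh + 2 * hl
  if (hh_weight != 0) {
    check_stat_shape(hh)
    fused <- fused + hh_weight * hh
  }
  as.vector(t(fused))
}

#' Weighted subband fusion, curvelet branch
#'
#' Elementwise `F1 + 3*F2 + 2*F3 + 2*F4`, flattened like [fuse_dwt()].
#'
#' @param f1,f2,f3,f4 128 x 6 `stat_matrix` inputs.
#' @return numeric vector of length 768.
#' @export
fuse_curvelet <- function(f1, f2, f3, f4) {
  check_stat_shape(f1, f2, f3, f4)
  as.vector(t(f1 + 3 * f2 + 2 * f3 + 2 * f4))
}

#' Zero-pad a fused feature vector to the square CNN input length
#'
#' Prepends and appends 8 zeros, taking 768 features to 784 = 28^2 so
#' each sample reshapes to the 28 x 28 network input grid.
#'
#' @param v numeric vector of length 768.
#' @return numeric vector of length 784.
#' @export
pad_features <- function(v) {
  if (length(v) != 768L) stop("pad_features() expects a length-768 vector")
  c(numeric(8L), v, numeric(8L))
}

#' Features for one (already augmented/enhanced or raw) patch
#'
#' Runs CLAHE, the selected decomposition branch, dense SIFT per band,
#' six-statistic aggregation, weighted fusion and zero padding, giving
#' the length-784 feature vector of one sample.
#'
#' @param p a `mammo_patch`.
#' @param method `"dwt"` or `"curvelet"`.
#' @param clahe_par a [clahe_params()].
#' @param dsift_par a [dsift_params()].
#' @param wavelet wavelet name for the DWT branch.
#' @param apply_clahe logical; set `FALSE` if `p` is already enhanced.
#' @return numeric vector of length 784.
#' @export
patch_features <- function(p, method = c("dwt", "curvelet"),
                           clahe_par = clahe_params(),
                           dsift_par = dsift_params(),
                           wavelet = "db4", apply_clahe = TRUE) {
  method <- match.arg(method)
  if (apply_clahe) p <- clahe(p, clahe_par)
  if (method == "dwt") {
    sb <- dwt2(p, wavelet)
    st <- lapply(sb$bands[c("LL", "LH", "HL")], function(b)
      band_statistics(dsift(b, dsift_par)))
    fused <- fuse_dwt(st$LL, st$LH, st$HL)
  } else {
    sb <- curvelet_bands(curvelet(p))
    st <- lapply(sb$bands, function(b) band_statistics(dsift(b, dsift_par)))
    fused <- fuse_curvelet(st$F1, st$F2, st$F3, st$F4)
  }
  pad_features(fused)
}

#' Assemble the sample-by-feature data matrix
#'
#' Runs the full feature pipeline over a list of labeled patches,
#' optionally after eight-fold augmentation, and stacks the resulting
#' rows: N x 785 with the class label in the final column. With
#' augmentation on, the 8 dihedral variants of source patch `i` occupy
#' consecutive rows and share `group = i`, recorded in the `group`
#' attribute so cross-validation can keep them in one fold.
#'
#' @param patches list of `mammo_patch`.
#' @param method `"dwt"` or `"curvelet"`.
#' @param augment_patches logical; apply the 8-fold augmentation first.
#' @param ... further arguments passed to [patch_features()].
#' @return numeric matrix N x 785 (`label` final column) with
#'   attributes `group` (source-patch index per row) and `method`.
#' @export
build_data_matrix <- function(patches, method = c("dwt", "curvelet"),
                              augment_patches = TRUE, ...) {
  method <- match.arg(method)
  stopifnot(length(patches) > 0)
  rows <- list(); groups <- integer(0)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (is.null(p$label)) stop("patch ", i, " has no label")
    variants <- if (augment_patches) augment(p) else list(p)
    feats <- tryCatch(
      lapply(variants, function(v)
        c(patch_features(v, method = method, ...), v$label)),
      error = function(e)
        stop("feature extraction failed at patch ", i, ": ",
             conditionMessage(e)))
    rows <- c(rows, feats)
    groups <- c(groups, rep(i, length(variants)))
  }
  M <- do.call(rbind, rows)
  dimnames(M) <- list(NULL, c(sprintf("f%03d", 1:784), "label"))
  attr(M, "group") <- groups
  attr(M, "method") <- method
  M
}
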