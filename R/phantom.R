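#' Phantom generator configuration
#'
#' Settings for the synthetic mammogram-like patch generator. Phantoms
#' stand in for clinical patches so that every stage of the pipeline can
#' be exercised with known ground truth: class 0 ("normal") is a
#' correlated-noise background texture, class 1 ("benign") adds one
#' smooth radially symmetric bright mass, class 2 ("malignant") adds an
#' irregular bright core with radial spicules.
#'
#' @param patch_size patch side length in pixels (>= 32).
#' @param background_texture_scale correlation length of the background
#'   texture in pixels (standard deviation of the smoothing kernel
#'   applied to white noise).
#' @param mass_radius_range two-element range of mass radii in pixels.
#' @param mass_contrast peak intensity offset of the mass above the
#'   background, in `(0, 1]`.
#' @param spicule_count_range two-element integer range of spicule counts
#'   for malignant masses.
#' @param noise_sd standard deviation of additive pixel noise in
#'   intensity units (image intensities live in `[0, 1]`).
#' @param seed integer seed controlling dataset generation.
#' @return a list of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(seed = 7)
#' p <- generate_patch(1L, cfg)
#' dim(p$pixels)
phantom_config <- function(patch_size = 128L,
                           background_texture_scale = 3,
                           mass_radius_range = c(12, 20),
                           mass_contrast = 0.5,
                           spicule_count_range = c(6L, 14L),
                           noise_sd = 0.05,
                           seed = 1L) {
  stopifnot(patch_size >= 32,
            mass_contrast > 0, mass_contrast <= 1,
            length(mass_radius_range) == 2,
            mass_radius_range[2] >= mass_radius_range[1],
            mass_radius_range[1] > 0,
            length(spicule_count_range) == 2,
            spicule_count_range[2] >= spicule_count_range[1],
            spicule_count_range[1] >= 1,
            noise_sd >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 background_texture_scale = background_texture_scale,
                 mass_radius_range = mass_radius_range,
                 mass_contrast = mass_contrast,
                 spicule_count_range = as.integer(spicule_count_range),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

new_patch <- function(pixels, label) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels),
            label %in% 0:2)
  structure(list(pixels = pixels, label = as.integer(label)),
            class = "mammo_patch")
}

#' @export
print.mammo_patch <- function(x, ...) {
  cls <- c("normal", "benign", "malignant")[x$label + 1L]
  cat(sprintf("<mammo_patch %dx%d, label %d (%s), range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$label, cls,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# correlated background texture: white noise smoothed to the requested
# correlation length, rescaled to a fixed mid-grey band
phantom_background <- function(n, scale, noise_sd) {
  base <- matrix(stats::rnorm(n * n), n, n)
  tex <- gauss_smooth(base, scale)
  s <- stats::sd(as.vector(tex))
  if (s > 0) tex <- tex / s
  clamp01(0.35 + 0.08 * tex + noise_sd * matrix(stats::rnorm(n * n), n, n))
}

# smooth radially symmetric mass with a Gaussian intensity profile
phantom_disc <- function(n, cx, cy, radius, contrast) {
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  contrast * exp(-d2 / (2 * (radius / 2)^2))
}

# spiculated mass: irregular (angularly modulated) bright core plus
# radial line segments with linearly decaying intensity
phantom_spiculated <- function(n, cx, cy, radius, contrast, n_spicules) {
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  r <- sqrt(yy^2 + xx^2)
  th <- atan2(yy, xx)
  # irregular core: radius modulated around the rim by random harmonics
  k <- sample(2:5, 2)
  amp <- stats::runif(2, 0.15, 0.3)
  ph <- stats::runif(2, 0, 2 * pi)
  rmod <- radius * (1 + amp[1] * cos(k[1] * th + ph[1]) +
                      amp[2] * cos(k[2] * th + ph[2]))
  core <- contrast * exp(-(r / (rmod / 1.6))^2)
  # spicules: narrow angular sectors whose intensity decays linearly
  # with distance from the core rim out to spike_len
  spic <- matrix(0, n, n)
  angles <- stats::runif(n_spicules, 0, 2 * pi)
  lens <- stats::runif(n_spicules, 1.2 * radius, 2.2 * radius)
  halfwidth <- 0.06
  for (i in seq_len(n_spicules)) {
    da <- abs(((th - angles[i] + pi) %% (2 * pi)) - pi)
    along <- (lens[i] - r) / lens[i]
    m <- da < halfwidth & r <= lens[i] & r > 0.2 * radius
    spic[m] <- pmax(spic[m], contrast * pmax(along[m], 0))
  }
  pmax(core, spic)
}

#' Generate one labeled phantom patch
#'
#' Draws a synthetic patch of the requested class using the current R
#' random-number stream (seed it with [set.seed()] for bit-identical
#' output, or use [generate_dataset()], which seeds from the config).
#'
#' @param cls class label: 0 = normal, 1 = benign, 2 = malignant.
#' @param cfg a [phantom_config()].
#' @return a `mammo_patch`: list with `pixels` (square matrix of
#'   intensities in `[0, 1]`) and integer `label`.
#' @export
generate_patch <- function(cls, cfg = phantom_config()) {
  if (!(length(cls) == 1 && cls %in% 0:2))
    stop("unknown class label: must be 0 (normal), 1 (benign) or 2 (malignant)")
  n <- cfg$patch_size
  img <- phantom_background(n, cfg$background_texture_scale, cfg$noise_sd)
  if (cls != 0) {
    radius <- stats::runif(1, cfg$mass_radius_range[1], cfg$mass_radius_range[2])
    # lesion-centred crop: the mass is the subject of the patch, as in
    # screening ROI patches; only a small placement jitter remains
    jit <- 0.06 * n
    cx <- n / 2 + stats::runif(1, -jit, jit)
    cy <- n / 2 + stats::runif(1, -jit, jit)
    mass <- if (cls == 1) {
      phantom_disc(n, cx, cy, radius, cfg$mass_contrast)
    } else {
      ns <- if (cfg$spicule_count_range[1] == cfg$spicule_count_range[2])
        cfg$spicule_count_range[1]
      else sample(cfg$spicule_count_range[1]:cfg$spicule_count_range[2], 1)
      phantom_spiculated(n, cx, cy, radius, cfg$mass_contrast, ns)
    }
    img <- clamp01(img + mass)
    attr_centre <- c(cx, cy)
  } else {
    attr_centre <- NULL
  }
  p <- new_patch(img, cls)
  p$mass_centre <- attr_centre
  p
}

#' Generate a balanced, shuffled phantom dataset
#'
#' @param n_per_class number of source patches per class (>= 1).
#' @param cfg a [phantom_config()]; `cfg$seed` makes the dataset (order
#'   and pixels) fully deterministic.
#' @return list of `3 * n_per_class` patches, class-balanced, shuffled.
#' @export
generate_dataset <- function(n_per_class, cfg = phantom_config()) {
  stopifnot(n_per_class >= 1)
  labels <- rep(0:2, each = n_per_class)
  old <- .Random.seed_exists()
  set.seed(cfg$seed)
  on.exit(restore_seed(old), add = TRUE)
  patches <- lapply(labels, generate_patch, cfg = cfg)
  ord <- sample.int(length(patches))
  patches[ord]
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write phantom patches as 8-bit PNG files plus a manifest
#'
#' Intensities in `[0, 1]` are quantized to 8 bits only at file-writing
#' time. The manifest is a two-column CSV (`filename,label`).
#'
#' @param patches list of `mammo_patch`.
#' @param out_dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the manifest path.
#' @export
write_patches <- function(patches, out_dir, prefix = "patch") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%04d.png", prefix, seq_along(patches))
  for (i in seq_along(patches)) {
    q <- round(clamp01(patches[[i]]$pixels) * 255) / 255
    png::writePNG(q, file.path(out_dir, files[i]))
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(
    data.frame(filename = files,
               label = vapply(patches, `[[`, integer(1), "label")),
    manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a patch manifest written by [write_patches()]
#'
#' @param manifest path to a `filename,label` CSV; image paths are
#'   resolved relative to the manifest's directory.
#' @return list of `mammo_patch`.
#' @export
read_patch_manifest <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "label") %in% names(tab)))
  dir <- dirname(manifest)
  lapply(seq_len(nrow(tab)), function(i) {
    px <- png::readPNG(file.path(dir, tab$filename[i]))
    if (length(dim(px)) == 3) px <- px[, , 1]
    new_patch(px, tab$label[i])
  })
}
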