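---
title: "Subband-descriptor CNN pipelines for mammogram patch classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subband-descriptor CNN pipelines for mammogram patch classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

`mammoband` classifies 128x128 grayscale mammogram patches into three
diagnostic classes — normal tissue, benign mass, malignant mass — with a
hand-engineered subband-descriptor representation feeding a small
convolutional network. Two sibling pipelines share every stage except the
decomposition: the wavelet pipeline (CNN-DW) and the curvelet pipeline
(CNN-CT).

For one labeled patch the stages are:

1. **Augmentation.** The eight dihedral variants (rotations by 0/90/180/270
   degrees, with and without a flip) are all kept, since lesion class is
   orientation-free. This multiplies every dataset by 8.
2. **CLAHE.** Contrast-limited adaptive histogram equalization over an
   8x8 grid of non-overlapping blocks (16x16 pixels each on the standard
   patch) with 256 histogram bins and a clip limit of 0.001 of the block
   pixel count (floored at one count). The per-block cumulative mappings
   are blended bilinearly between block centres. See "CLAHE behaviour"
   below — this step's parameters matter more than any other in the
   pipeline.
3. **Decomposition.** Either a one-level separable 2-D DWT (orthonormal
   Daubechies filters, periodic boundary), giving LL/LH/HL/HH subbands of
   64x64; or a curvelet frame, collapsed to four scale bands F1-F4
   resampled to the same 64x64 geometry.
4. **Dense SIFT.** 128-dimensional gradient-orientation descriptors
   (4x4 spatial bins x 8 orientation bins) on a fixed grid with step 4 and
   spatial bin side 5, L2-normalized with the 0.2 clamp-and-renormalize.
5. **Statistics.** Per band, the 128 x K descriptor matrix is summarized
   across keypoints by six statistics per descriptor dimension — kurtosis,
   mean, skewness, energy (mean square), maximum, standard deviation —
   giving a 128 x 6 matrix.
6. **Fusion and padding.** The per-band statistic matrices are combined by
   the fixed integer weights `3*LL + 2*LH + 2*HL` (wavelet branch; HH is
   excluded by the published rule, re-includable via `hh_weight`) or
   `F1 + 3*F2 + 2*F3 + 2*F4` (curvelet branch), flattened row-major to 768
   values and zero-padded by 8 on each side to 784 = 28 x 28.
7. **CNN.** The 784-vector is reshaped to a 28x28 grid and passed through
   two valid convolution + 2x2 max-pool stages (16 kernels of 7x7, then 16
   of 5x5), a 128-wide fully connected layer with dropout 0.55, and a
   3-way softmax trained by mini-batch SGD with momentum.
8. **Head.** Either the softmax itself, or a one-vs-rest linear SVM fit on
   the penultimate (fully connected) activations — the configuration that
   performed best in the source experiments.
9. **Evaluation.** Per-class one-vs-rest accuracy, PPV, NPV, sensitivity,
   specificity, MCC and rank-statistic ROC-AUC, plus the overall
   multi-class accuracy (trace of the 3x3 confusion table over N). The two
   notions of accuracy are reported separately and never conflated.

## The phantom generator

No clinical data ship with the package. The `phantom` module generates
lesion-centred synthetic patches with known ground truth:

- **normal** — correlated background texture: Gaussian white noise smoothed
  to a 3-pixel correlation length, scaled to a mid-grey band, plus
  additive white noise (sd 0.05);
- **benign** — the same texture plus one radially symmetric Gaussian-profile
  bright disc (radius 12-20 px, peak contrast 0.5);
- **malignant** — an irregular bright core (radius modulated by random
  low-order harmonics) with 6-14 radial spicules whose intensity decays
  linearly along their length.

Masses are centred in the patch with a +/-6% jitter, emulating
screening-style ROI crops in which the finding is the subject of the
patch; a generator that scattered masses across the field would emulate a
detection problem instead, which is not what patch classification datasets
look like. Spiculation is the minimal morphological feature separating
malignant from benign margins, so the phantom discriminates the three
classes by exactly the cues the real task uses: presence of a mass, and
margin character.

What the phantom does **not** emulate: parenchymal anatomy (ducts,
vessels, pectoral muscle), scanner-specific noise spectra, calcification
clusters, and the intensity statistics of film digitization. Passing the
pipeline's tests on phantoms therefore demonstrates that the
implementation is correct and that the representation can separate
mass-morphology classes under controlled conditions — not that clinical
accuracy figures transfer.

Intensities are kept in [0, 1] internally and quantized to 8 bits only
when writing PNG files.

## CLAHE behaviour and why it is documented here

"Blocks of size 8 x 8" admits two readings: 8x8-pixel blocks (256 tiny
tiles on a 128-pixel patch) or an 8x8 *grid* of tiles (16x16 pixels
each) — the tile-count convention of the standard adaptive-equalization
toolboxes, whose default tile grid is exactly 8x8. The package defaults
to the grid reading, for a reason one can check without any classifier:
with 8x8-pixel blocks a clip of one count is four times the uniform
density of a 64-pixel, 256-bin histogram, so the clip never engages and
the "contrast limited" method degenerates to unclipped local
equalization — a local rank transform that amplifies fine-grain noise in
flat regions while compressing mass contrast. With the 16x16-pixel tiles
of the grid reading the same clip sits at the uniform density, engages
maximally, and produces the mild, limited enhancement the method's name
promises. `clahe_params()` exposes the block size, so the literal pixel
reading is one argument away; the `clip_limit = 1` setting reduces to
plain adaptive histogram equalization and is oracle-tested against an
independently coded implementation.

Gaussian pre-smoothing of the bands was evaluated as a mitigation and
rejected: at the scales that suppress the amplified noise it also blurs
the few-pixel mass structure in the half-size subbands, and end-to-end
accuracy did not improve.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `clahe_params(block_size)` | 16 px | CLAHE block side (8x8 tile grid on a 128 px patch) |
| `clahe_params(clip_limit)` | 0.001 | clip as fraction of block pixels, floor 1 count |
| `dsift_params(step)` | 4 px | keypoint grid spacing |
| `dsift_params(bin_radius)` | 5 px | spatial bin side; descriptor support is 20 px |
| `cnn_config(dropout)` | 0.55 | dropout on the fully connected layer |
| `cnn_config(activation)` | tanh | saturating nonlinearity (see below) |
| `cnn_config(learning_rate)` | 0.01 | SGD step, momentum 0.9, batch 32 |
| `svm_fit(C)` | 1.0 | soft-margin cost of the head |

**Activation.** The published description admits both the logistic sigmoid
and tanh. With 55% dropout on the fully connected layer, the sigmoid
variant of this small network fails to learn at all (training accuracy
stays at chance even when asked to memorize 60 samples): its non-zero-
centred, low-gradient activations compound with the dropout noise. The
tanh variant memorizes the same set perfectly and trains stably at
learning rate 0.01, so tanh is the default and sigmoid remains selectable.

**Keypoint count.** On a 64x64 band with step 4 and support 20 the grid
yields 12x12 = 144 keypoints. All six statistics are K-invariant (energy
is a mean of squares, not a sum), so configurations with other band sizes
or grid spacings produce identically shaped features.

**Statistic conventions.** Skewness and kurtosis use population moments;
kurtosis is non-excess (a normal sample tends to 3); zero-variance
dimensions yield skewness = kurtosis = 0; the zero descriptor vector
normalizes to zero. These conventions are oracle-tested.

## Numerical choices

- **DWT.** One analysis level as an orthogonal matrix operator with
  periodic boundary handling: perfect reconstruction and energy
  conservation hold to machine precision for the orthonormal Daubechies
  family (haar/db2/db4/db8; default db4).
- **Curvelet.** Realized as an undecimated tight frequency-wedge frame:
  Meyer-style radial ring windows (squares telescoping to one) times
  smooth angular windows (squares partitioning unity; 8 wedges per detail
  scale), four scales. Coefficients stay at full grid size, which makes
  the frame exactly tight — synthesis is error-free to machine precision —
  and keeps orientations aligned for the root-sum-square magnitude
  aggregation into F1-F4. A decimated wrapping-style transform would use
  less memory per frame, but at these patch sizes (128x128) the full-grid
  frame costs a few megabytes and removes every wrapping/interpolation
  failure mode.
- **Pooling ties.** Max-pool backward routes gradient to the first maximal
  quadrant (deterministic tie-break).
- **Degenerate metrics.** PPV/NPV/sensitivity/specificity with an empty
  denominator are defined as 0 and flagged; MCC with a zero denominator is
  0. Constant predictors therefore evaluate without error.
- **Standardization.** Features are z-scored per column with statistics
  from the training split only; zero-variance columns get unit scale.
- **Determinism.** Every stochastic step (phantom sampling, fold dealing,
  weight init, batch shuffling, dropout masks) derives from an explicit
  seed; two runs with the same configuration are bit-identical.

## Cross-validation without augmentation leakage

The eight dihedral variants of one source patch are nearly duplicate
samples; letting them straddle a train/test boundary inflates every
metric. `make_folds()` therefore stratifies by class but deals *source
patches* (groups), never rows, and `cross_validate()` refuses plans in
which a group spans folds. The 10-fold protocol retrains the CNN in every
fold by default; `retrain_cnn = FALSE` refits only the SVM head, which is
faster but lets the shared representation see every row.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script runs use 60 source patches per class
(1440 rows after augmentation) for the held-out smoke evaluation, 30
training epochs, and tiny reduced configurations (12x12 input, 2+2
kernels) for gradient checks. These sizes were chosen so the full suite
exercises every stage end to end in a few minutes on one CPU while leaving
the statistical conclusions unchanged at larger n.

## Known limitations

- The phantom's difficulty is not calibrated to IRMA; published accuracy
  figures on clinical data are out of reach of any synthetic surrogate and
  are not reproduced here.
- The curvelet branch aggregates complex coefficients to magnitudes before
  the statistics, discarding phase.
- The CNN is a faithful small-scale reimplementation (two conv/pool
  stages, SGD with momentum); it makes no claim to modern architecture or
  optimizer choices.
- CLAHE at the published parameterization approaches unclipped local
  equalization on continuous-valued data (see above); on heavily
  quantized 8-bit data with many tied gray levels the clip engages more.
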