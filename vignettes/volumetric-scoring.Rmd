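---
title: "Volumetric Lund-Mackay scoring with semi-supervised segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric Lund-Mackay scoring with semi-supervised segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sinusct)
```

This vignette documents the methods behind `sinusct`: the scoring
definitions, the synthetic phantom generator and its calibration, the
segmentation network and its numerics, the semi-supervised training loop,
and the surface reconstruction, together with the reasoning behind the main
design choices and their limitations.

## 1. Scores

Chronic rhinosinusitis staging on CT conventionally uses the Lund-Mackay
system: each of 12 regions (left/right maxillary, anterior ethmoid,
posterior ethmoid, frontal, sphenoid sinuses and ostiomeatal complexes) is
graded 0 = clear, 1 = partial, 2 = complete opacification, with the
ostiomeatal complex (OMC) restricted to 0/2. `sinusct` implements two
scores on top of a per-region opacification *ratio*
`disease volume / total cavity volume` measured from a 3D segmentation:

* **TLMs** (`tlms()`): an automated traditional score. The ratio is
  discretised by two cut-offs, `partial_low = 0.05` and
  `complete_high = 0.95` — ratios at or below the low cut grade 0, at or
  above the high cut grade 2, otherwise 1. The OMC is graded 0 or 2 with a
  0.5 cut. The cut-offs absorb partial-voxel and segmentation noise at the
  extremes so that a clear or fully opacified sinus is graded as such.
* **VMLMs** (`vmlms()`): the continuous volume-based score,
  `VMLMs = sum over regions of 2 * ratio`, on `[0, 24]`. Scaling by 2 puts a
  fully opacified region at its traditional maximum grade, so VMLMs and
  TLMs coincide at the extremes (all ratios 0 or 1) and are directly
  comparable in between.

VMLMs inherits three properties that the test suite asserts as invariants:
it is bounded in `[0, 24]`, monotone non-decreasing in every region's
ratio, and additive (the total is exactly the sum of the per-region
sub-scores).

`reference_score_table()` ships per-region mean sub-scores for a surgical
and a non-surgical reference group, used by the cohort generator's
calibration and by the acceptance checks of the aggregation arithmetic.

## 2. Phantom generator

Real labelled sinus CT cannot be shipped with a package, so `sinusct`
generates synthetic phantoms with exact ground truth. A phantom
(`phantom_spec()` + `generate_phantom()`) is a 3D Hounsfield-unit volume
built from 12 disjoint ellipsoidal cavities in a canonical head layout:

* **Tissue model.** Background soft tissue at `hu_mucosa` (+40 HU), cavity
  interiors at `hu_air` (-1000 HU), and a bone shell (+700 HU) occupying
  normalised radii `(1, bone_shell_scale]` around each cavity. Additive
  Gaussian noise (`noise_sd`, default 15 HU) models reconstruction noise.
* **Disease model.** Opacification fills each cavity *wall-inward*: the
  voxels with the largest normalised radius (closest to the mucosal wall)
  are converted to soft-tissue intensity until the prescribed fraction of
  the cavity volume is reached. This mimics mucosal thickening progressing
  to full opacification and guarantees the ground-truth ratio matches the
  prescription to within one voxel.
* **Ground truth.** The voxel label map (13 classes: background + 12
  regions) and a per-region truth table (voxel counts, mL volumes, ratio,
  VMLMs/TLMs sub-scores) are emitted alongside the volume; rasterisation
  and truth are computed from the same geometry, so they agree exactly.
* **Determinism.** Identical spec and seed give bit-identical volumes.
  NIfTI round-trips (`write_phantom()`, `read_ct_volume()`) preserve data
  and spacing.

`generate_cohort()` wraps this in a subject-level model
(`cohort_model()`): sex (with sex-dimorphic cavity volumes calibrated to
`cohort_volume_table()`), height (contributing a known share of cavity
volume variance — the coefficient is exposed via `cohort_height_coef()` so
regression estimators can be validated by parameter recovery), a
surgical/non-surgical opacification profile calibrated to
`cohort_opac_table()` via moment-matched Beta distributions, and pre/post
symptom scores with a known responder rule. `specs = FALSE` skips
per-subject phantom-spec construction when only the tabular records are
needed (e.g. 500-subject regression studies run in well under a second).

**Limitations.** Cavities are ellipsoids, not true sinus anatomy; there is
no partial-volume blurring at interfaces, no beam hardening, and no
anatomical variation beyond volume scaling and centre jitter. The phantoms
are calibrated to published group-level volumes and opacification ratios,
not to individual scans.

## 3. Segmentation network

Segmentation is 2D slice-wise (coronal reslices via `reslice_coronal()`),
restacked into a 3D label map with `stack_segmentations()`. The network
(`seg_config()`, `build_segnet()`) is a compact encoder-decoder:

* a stem convolution (3x3, stride 1) with batch normalisation and ReLU;
* `depth` encoder stages, each a residual block of two depthwise-separable
  convolutions (depthwise 3x3 stride 2 then 1, each followed by a
  pointwise 1x1), batch normalisation, ReLU, and a squeeze-and-excitation
  (SE) gate whose hidden excitation uses the **Mish** activation
  (`x * tanh(softplus(x))`); the shortcut is a strided 1x1 projection;
* an atrous spatial pyramid pooling (ASPP) head: parallel 3x3 convolutions
  at the configured dilation rates plus a global-average-pool branch,
  fused by a 1x1 convolution (a single 3x3 convolution at dilation `d` has
  impulse-response support `d*(k-1)+1`; the test suite asserts this on
  impulse inputs);
* a bilinear decoder with skip connections from the encoder stages and a
  1x1 classification head over the 13 classes.

**Numerics.** All forward and backward kernels are hand-written in
Rcpp/RcppArmadillo: convolution as im2col + GEMM, depthwise convolution as
direct loops, bilinear resampling with explicit gradients, batch
normalisation with train/eval modes and running statistics, and a fused
softmax cross-entropy that supports an ignore label (-1) and per-class
weights. Optimisation is Adam. Correctness is established by
finite-difference gradient checks through the entire network and by
hand-computed oracles for the individual kernels (exact convolution
arithmetic, Mish values to 17 significant digits, SE identities such as
"zero excitation weights gate every channel at exactly 1/2").

**Class imbalance.** Sinus regions occupy a small fraction of the pixels;
with unweighted cross-entropy the network collapses to predicting
background (training loss falls while held-out Dice stagnates).
`train_segnet()` therefore defaults to inverse-square-root-frequency class
weights, mean-normalised and clamped to `[0.25, 25]`. The square root is a
deliberate compromise: full inverse-frequency weighting over-amplifies the
rarest classes' label noise, while the square root preserves ordering but
compresses the dynamic range; the clamp bounds the worst case.

## 4. Semi-supervised self-training

Labelled segmentations are scarce; unlabelled CT is plentiful. The
package's semi-supervision is classic confidence-filtered self-training:

1. `make_split()` partitions subjects deterministically into labelled
   train/validation and unlabelled self-training/test sets (floor
   arithmetic: 50 labelled at 8:2 gives 40/10; 20% of 125 unlabelled
   gives 25).
2. `pseudo_label()` runs the current model over unlabelled slices and
   keeps each pixel's argmax class only where the softmax confidence
   reaches `tau`; everything else gets the ignore label. Coverage (the
   retained fraction) is monotone non-increasing in `tau` — a property the
   tests assert.
3. `fit_loss_mixture()` fits a two-component Gaussian mixture to
   per-sample losses by EM (log-likelihood is asserted non-decreasing) and
   flags the high-loss component as noisy; `self_train()` zeroes the
   sample weight of noisy pseudo-labelled slices.
4. The model is retrained on labelled + retained pseudo-labelled data and
   the cycle repeats for `rounds` rounds, re-labelling with the improved
   model each time. An optional entropy term (`lambda`) sharpens
   predictions on low-confidence pixels.

Two practical points that the package's experiments surfaced: self-training
only helps once the warm-up model is good enough that its pseudo-labels
are mostly correct (against a badly undertrained baseline it amplifies its
own errors), and pseudo-labels should be refreshed frequently — many
gradient steps against stale pseudo-labels let the model drift toward the
labels' errors.

## 5. Volumetry and surfaces

`region_volumes()` partitions each region of a (predicted or ground-truth)
label map into air and disease by an HU threshold (default -400, midway
between air and soft tissue) inside the original volume, and reports voxel
counts, mL volumes and the opacification ratio per region — the direct
input to `vmlms()`/`tlms()`.

`reconstruct_surface()` extracts a region's closed boundary surface as a
triangle mesh by cuberille (voxel-face) triangulation: every voxel face
that separates the region from non-region contributes two outward-oriented
triangles with vertices at voxel corners in mm. Two consequences are
asserted by tests: the mesh is watertight (every edge is shared by exactly
two faces) and, by the divergence theorem, `mesh_volume()` equals the
voxel-counted volume *exactly*. A marching-cubes surface would look
smoother but only approximates the enclosed volume; for a package whose
endpoint is volumetry, exactness was preferred. `write_stl()` exports
ASCII STL.

## 6. Evaluation statistics

`seg_metrics()` computes the confusion matrix and per-class Dice and IoU
(classes absent from both prediction and reference are excluded from the
means), mean region Dice, MIoU and pixel accuracy; the tests assert the
algebraic identity `dice = 2*iou/(1+iou)` on random grids. `roc()`
computes the trapezoid ROC AUC — asserted equal to the all-pairs rank
statistic (the probability a positive outscores a negative, ties counted
half) — plus the Youden-optimal cut-point; results are cross-checked
against `pROC` where installed. `responder()` implements a pre/post
symptom-score improvement rule, and `stat_battery()` bundles Welch/Student
t-tests, ANOVA and linear regression over cohort records.

## 7. Reproducibility

Everything stochastic is seeded: phantoms, cohorts, weight initialisation,
batch shuffling, splits. The acceptance script
(`scripts/acceptance.R --seed <int> --out <path>`) re-runs the main
computations against the installed package and writes the headline numbers
as JSON; the test suite (`tests/testthat/`) contains unit oracles,
property tests and acceptance tests that train small models end to end.
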