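---
title: "Multi-slice MRI data generation and 3D-CNN classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-slice MRI data generation and 3D-CNN classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Case-control neuroimaging studies — here, classifying autism spectrum
disorder (ASD) against typical controls (TC) — start from raw structural
MRI (one 3D volume per subject) and functional MRI (a 4D series of volumes
over time). Before any classifier sees the data, a pipeline must decide how
to split subjects, how to bring intensities onto a common scale, and how to
reduce the raw volumes to model inputs: 2D slices for image backbones, or
3D (mean) volumes for a volumetric network. `neuroslice` implements that
pipeline as composable, individually testable stages, together with a
compact 3D convolutional classifier and a synthetic phantom cohort that
makes every stage exercisable without downloading subject data.

## Subject-level splitting

Per-subject sample generation multiplies each subject into many training
images. If the train/test split were drawn at the *image* level, slices of
one subject would appear on both sides and test performance would be
inflated by identity leakage rather than reflecting generalisation. The
split here is therefore drawn at the *subject* level, stratified by class,
before any generation: per class the test set receives
`floor((1 - fraction) * n)` subjects. With the default fraction 0.8 a
79-ASD / 105-TC cohort yields 64/84 training and 15/21 test subjects, and
with `n` slices per subject the generated image counts per cell are exactly
`n_subjects * n`. Every generated dataset records subject provenance so the
disjointness of the two partitions is assertable after the fact; the test
suite does assert it.

## FCM tissue-mean intensity normalization

Raw MRI intensities are in arbitrary scanner units. The normalizer clusters
the foreground (nonzero) voxel intensities with fuzzy c-means — memberships
$u_{ij} \propto d_{ij}^{-2/(m-1)}$ normalised per voxel, centroids
$c_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m$, alternating until the
largest centroid change falls below `tol` — then divides the whole volume
by the mean intensity of the voxels hard-assigned to the reference tissue.
With `k = 3` classes on T1-like contrast the three clusters act as
CSF/GM/WM proxies and the highest-centroid cluster is white matter, so
after normalization the WM mean equals 1 and all other tissues are
expressed relative to it. Defaults: `k = 3`, fuzzifier `m = 2`,
`tol = 1e-5`, at most 100 iterations, deterministic initialisation at
evenly spaced intensity quantiles.

Two design points deserve note. First, division uses the *hard-assigned
tissue mean* rather than the fuzzy centroid: the tissue mean is the
quantity with the physical interpretation ("the average intensity of white
matter"), it is robust to the residual fuzziness of the converged
memberships, and on a noiseless phantom it makes normalization exact.
Second, the foreground mask is simply the nonzero voxels: the phantoms have
exactly-zero background by construction, and real scans are assumed
skull-stripped upstream. The operation is scale-invariant
(`normalize(a*V) = normalize(V)`) and idempotent, both verified in tests.

## Slice generation and temporal windows

The axial, coronal and sagittal planes map to the z, y and x array axes.
The "middle" index of an axis of extent $d$ is $\lfloor d/2 \rfloor$
(0-based), and the centred $n$-slice window is the half-open interval
$[c - \lfloor n/2 \rfloor,\; c - \lfloor n/2 \rfloor + n)$. This convention
is forced by its own worked instance: a 176-volume series with $n = 30$
must give $[73, 103)$, i.e. $88 - 15 = 73$. Slices are resized to 224 x 224
(the standard input resolution of natural-image backbones) by bilinear
interpolation and exported as 8-bit PNGs under a per-slice min–max map —
deterministic and contrast-preserving within each slice; a constant slice
maps to zero.

For 4D series, three temporal strategies are provided: the centred `mid_n`
window, `all` timepoints, and `all_trim`, which drops the first and last 10
timepoints to guard against acquisition-onset and -offset artefacts. The
selected window is collapsed to a 3D *temporal mean image*, which is then
normalized like a structural volume.

Resampling (2D bilinear, 3D trilinear, in-plane rotation) is implemented on
one shared linear-interpolation core with align-corners semantics, chosen
so that equal-size resampling is an exact identity and constants are
preserved exactly — properties the test suite relies on; an independent
image library serves as a cross-check oracle in the tests.

## The 3D-CNN

The classifier is four convolutional blocks — Conv3D with 3 x 3 x 3 kernels
and same padding, ReLU, 2 x 2 x 2 max pooling, then batch normalization —
with 64, 64, 128 and 256 filters, followed by global average pooling, a
512-unit ReLU dense layer with dropout 0.3, and one sigmoid output unit
(ASD = 1). Training uses binary cross-entropy and Adam with learning rate
0.001; the reference recipe is 50 epochs. Batch size defaults to 8, a
desk-scale choice for 3D inputs. Inputs are single-channel volumes whose
extents must each be at least 16 so that four 2x poolings remain valid;
volumes of other sizes are brought to the configured input resolution
(default 32^3 in the bundled pipeline configurations) by trilinear
resampling.

Two implementation details matter for correctness and speed:

* **Fused training step.** The whole forward + backward pass over a
  mini-batch runs as a single compiled call (im2col + GEMM convolutions,
  single-precision activations); only parameters, gradients and batch-norm
  statistics cross into R, where Adam updates are applied in double
  precision. A double-precision, layer-by-layer reference path exists
  alongside; the tests check the reference against finite-difference
  gradients and the fused path against the reference.

* **Batch-norm recalibration.** With small cohorts the number of gradient
  steps is far too small for exponentially averaged running statistics to
  track the rapidly changing activation distributions, which makes
  inference-mode normalization stale and can destroy test accuracy even
  when training-mode predictions are perfect. After every epoch the
  package therefore recomputes the batch-norm population statistics of the
  training set under the current weights with one forward-only pass (the
  same recalibration used with stochastic weight averaging) and uses those
  as the inference statistics.

Augmentation — a random horizontal/vertical flip and a rotation uniform in
±36°, a tenth of a full turn — is applied to training samples only, and is
off by default for the 3D-CNN; it is part of the transfer-learning recipe.

## Transfer-learning head

Pretrained image backbones are represented by a minimal contract: a
callable from a 224 x 224 x 3 image to a fixed-length feature vector. The
classification head is a single dense sigmoid unit on those features,
trained with the same optimizer settings. Only frozen backbones are
trainable end-to-end here — an opaque feature extractor cannot be
back-propagated through — which matches the intended use of training only
the replacement top layer. Shipping actual pretrained transformer weights
is out of scope; a small deterministic stub backbone (coarse pooling
followed by a fixed random projection) validates the harness.

## The phantom cohort

The synthetic generator emulates exactly the statistical structure the
pipeline assumes and nothing more: nested axis-aligned ellipsoids —
background 0, a CSF shell at 100, grey matter at 250, white matter at 500,
a 0.2 : 0.5 : 1.0 ratio — with additive Gaussian noise (default sd 25, 5%
of the WM mean) *inside the brain only*, so the background stays exactly
zero like a skull-stripped scan. Ellipsoid geometry was chosen because
compartment membership is known analytically, which permits exact
noiseless assertions. Per-subject intensity variability is modelled by a
log-normal multiplicative jitter (sd 0.02). Class structure: ASD phantoms
have grey-matter intensity scaled by `1 + class_effect` (default 0.1) in
3D, and in 4D a regional cosine signal of amplitude 50 (10% of WM) in the
innermost compartment, completing exactly one period over the series
(default T = 176), against amplitude 0 for controls.

The cosine time course is the one deliberate subtlety: its mean over the
full series is zero, so the all-timepoints mean image carries almost no
class signal, while a centred 50-of-176 window straddles the trough and
retains about 86% of the amplitude. The phantom cohort therefore
reproduces, by construction, the qualitative ordering in which the
centred-window strategy is the most informative and the full-series mean
the least — which is what makes it a meaningful end-to-end testbed for the
windowing machinery rather than an arbitrary classification task.

What the phantoms do *not* model: anatomy beyond nested ellipsoids, Rician
noise statistics, bias fields, motion, hemodynamics, registration error,
or any overlap in the class distributions beyond the noise and jitter
above. A classifier that reaches high accuracy on this cohort has been
shown to learn a strong, known signal through the full pipeline — nothing
more. Passing the bundled end-to-end test is a statement about the
software, not about diagnostic performance on real subjects.

## Problem sizes and numerical choices

The bundled end-to-end configurations run the phantom cohorts at 64^3
voxels for structural slice generation and 32^3 for functional training
with 8 epochs — sizes chosen so the full suite runs comfortably on a
single CPU while keeping every count and invariant at full cohort scale
(184 and 80 subjects). Other constants: batch-norm epsilon 1e-3; Adam
(0.9, 0.999, 1e-7); cross-entropy clipping 1e-7 with natural logarithms,
keeping evaluation loss comparable to the training objective; decision
threshold 0.5 with ties classified positive; F1 defined as 0 when
precision + recall is 0. Volumes are stored as float32 NIfTI; a
single-timepoint series is kept 4D on disk by restoring the header's
dimensionality field, which the writer would otherwise canonicalise to 3D.

## Known limitations

Training is single-threaded and desk-scale; there is no learning-rate
schedule, early stopping, or cross-validation (a single subject-level
train/test split mirrors the evaluation design). The per-epoch history
reports test metrics for monitoring, but model selection on those values
would require a third split, which is deliberately not provided. Slice
datasets hold file paths rather than pixel data; the 2D PNG datasets are
intended for external backbones and are not consumed by the 3D-CNN path.
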