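---
title: "Methods: two-branch point-voxel segmentation of plant point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-branch point-voxel segmentation of plant point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffnet)
```

## The problem

Modern scanners produce plant point clouds with hundreds of thousands to
millions of points per scan. Organ-level semantic segmentation — labelling
every point as ground, stem or leaf — is the entry point to automated
phenotyping (leaf area, stem height, growth tracking). Two properties make
the task hard:

* **Scale drift.** A plant scanned daily grows by an order of magnitude over
  a few weeks, so any method tied to a fixed metric resolution sees early
  scans as a few voxels and late scans as millions.
* **Class imbalance and thin structures.** The stem is a few percent of the
  points (about 5.5 % in maize-like training scans), and a thin leaf sheet
  passing near the stem is locally almost indistinguishable from it.

`ffnet` implements a two-branch network for this setting. The *voxel branch*
captures multi-scale context through sparse 3D convolution on an adaptively
sized grid; the *point branch* keeps per-point detail that voxelization
would blur; an attention module fuses the two per point. The whole cloud is
processed at once — no block cutting, no down-sampling.

## Adaptive voxelization

`fit_grid()` places a cubic-voxel grid with a fixed number of voxels
(default 128) along the longest bounding-box axis. The voxel edge therefore
scales with the plant, and a cloud re-scanned at a larger size occupies the
grid with the same occupancy pattern — this is the scale-adaptivity the
architecture relies on, realised as a deterministic rule (the alternative,
a fixed metric edge, is what it replaces). Cells are half-open `[lo, hi)`
with the grid's max corner clamped into the last cell, so every point maps
to exactly one voxel. Anisotropic (per-axis) voxels are representable in
the `grid_spec` but cubic voxels are the default; nothing in the engine
assumes cubicity.

`voxel_assign()` keeps the active (occupied) voxels only, as a
lexicographically sorted coordinate list plus a point-to-voxel index map.
`scatter_max()` / `voxel_gather()` are the two reductions both branches
use: a symmetric per-voxel max (permutation-invariant, the mini-PointNet
convention; a mean is available behind `reduce = "mean"`) and the inverse
broadcast. `coarsen()` floor-divides voxel coordinates, and composes:
coarsening twice by 2 equals coarsening by 4.

## The voxel branch

Each point `p_i` is first described by a 9-dimensional adaptive feature

```
[ p_i ;  p_i - centroid(V_i) ;  p_i - v_i ]
```

where `V_i` is the set of points sharing `p_i`'s voxel and `v_i` is the
voxel's minimum ("border") corner. The middle term is implemented as the
offset from the member **centroid** rather than from a raw coordinate sum:
a sum of member coordinates is not translation-meaningful (it scales with
occupancy), while the centroid offset is a proper local geometry descriptor.
The reference corner can be switched to the voxel centre via
`ffnet_config(voxel_corner = "center")`. A shared two-layer perceptron and
a per-voxel max produce the initial voxel features.

The encoder–decoder is a U-Net over sparse grids:

* **Submanifold sparse convolution.** Convolutions are evaluated only at
  active sites and outputs are restricted to the same sites, so sparsity
  never dilates with depth. A *rulebook* lists, per kernel offset, the
  (input site, output site) pairs; convolution is gather → per-offset
  matrix product → scatter-add. Site lookup uses an exact integer-tuple
  key (no lossy hashing): correctness is preferred over micro-optimisation
  at the scales this package targets.
* **ASPC blocks.** Each residual block runs two parallel asymmetric paths —
  a `3×1×3` followed by a `1×3×3` kernel, and the same pair in the other
  order — sums them with an identity shortcut (a `1×1×1` projection when
  widths change), with per-channel normalisation and a leaky rectifier
  (slope 0.1) around each convolution. Asymmetric kernels concentrate
  capacity on the horizontal and vertical structures that dominate plant
  geometry (vertical stems, spreading leaves) at fewer weights than a full
  `3×3×3` kernel; the exact shapes are configurable constants.
* **Downsampling** is a strided sparse convolution (kernel 2, stride 2),
  chosen over pooling so the reduction is learned.
* **ISPC blocks.** The decoder inverts each strided convolution by
  transposing its stored rulebook, which restores the encoder's active-site
  set *exactly* (not approximately); skip features are concatenated and
  mixed by a `1×1×1` convolution.

Default widths are 32–64–128–256–256 (four strided stages, four ISPC
blocks); the tests and the acceptance harnesses use a two-stage 16/32
configuration, which is ample for the synthetic geometry.

## The point branch and fusion

A mini-PointNet (shared per-point perceptron, no cross-point mixing) embeds
coordinates normalised to the grid's unit box — normalisation keeps the
point branch stable across growth stages, while the raw coordinates feed
the adaptive voxel feature above. A Voxel-PointNet (VPN) block per encoder
stage then gathers that stage's voxel features back to the points, treating
the voxel as the point's neighbourhood (an O(n) substitute for k-nearest
neighbours), concatenates, mixes through a shared layer and adds a residual
shortcut. Stacking one VPN per stage gives every point multi-scale context.

Fusion is channel-wise attention: each branch's feature vector passes
through its own MLP producing `2C` scores; the two score vectors are summed,
reshaped to `(2, C)` and softmax-normalised over the branch axis. The
resulting weights satisfy `alpha_v + alpha_p = 1` per channel, so the fused
feature is a convex, channel-wise blend bounded by the two branch values.
With two branches the softmax reduces to a sigmoid of the score difference,
which is how it is computed. A scalar-per-branch variant
(`scalar_attention = TRUE`) is provided because the score width is a free
design choice; the per-channel form is the default. The point head
classifies the fused features; a second head classifies the decoder's
voxel features.

## Loss and metrics

Class weights are reciprocal class frequencies computed **once over the
full training set** (not per batch, keeping the loss scale deterministic);
classes absent from the training labels get weight zero. The voxel head is
trained with weighted cross entropy plus the Lovász-softmax loss — the
Lovász extension of the Jaccard (1 − IoU) loss, averaged over the classes
present in the batch, which directly optimises the evaluation metric and is
stable for minority-class batches. The point head uses weighted cross
entropy alone. The total loss is their unweighted sum. Voxel-level ground
truth is the majority vote of member-point labels, ties to the smaller
class id. In the cross-entropy the true class enters as a one-hot
indicator (standard cross entropy), not as a soft target.

Evaluation reports the confusion matrix, per-class
`IoU = TP / (TP + FN + FP)` and their arithmetic mean (mIoU). A class
absent from both truth and prediction scores a vacuous IoU of 1; absent
from truth but predicted scores 0. This convention only matters for
degenerate desk-scale tests.

## Training protocol

Adam at a constant learning rate of 0.001 (no schedule), batches of four
whole clouds with gradient averaging, 200 epochs by default. Gradient norm
is clipped at 10 as a guard before the non-finite-loss abort. Normalisation
layers use batch statistics in both training and inference; with whole
clouds as batches this is fully deterministic and avoids running-average
state. Epoch-level shuffling uses a generator seeded from the config seed,
weight initialisation is fan-in-scaled uniform under the same seed, and a
fixed seed reproduces checkpoints bit-for-bit in single-threaded mode. The
best-training-mIoU checkpoint is retained.

## The synthetic generator

`generate_plant()` builds labelled clouds from a parametric recipe: a
planar ground patch at `z = 0`, a solid, slightly curved vertical stem
cylinder, and leaf blades attached at distinct stem heights — rectangular
sheets bent along their length by a droop angle with a shallow transverse
fold, reproducing the thin-sheet geometry that makes leaf/stem confusion
hard. Organ point counts are multinomial at the target fractions (default
stem share 5.5 %, ground and leaf splitting the remainder evenly),
mimicking scanner density variation; Gaussian coordinate noise is added on
top. An optional whorl places short leaves around the stem tip, emulating
the stem-surrounded-by-leaves failure mode. `generate_growth_series()`
scales heights, leaf lengths and point budgets by `(1 + rate)^day` to
emulate daily scans of a growing plant. Generation is deterministic given
the recipe and restores the caller's RNG state.

What the generator does **not** emulate: occlusion, sensor-specific noise
anisotropy, petioles and flowers, touching leaves from neighbouring plants,
and real label noise near organ boundaries. Tests passing on synthetic
plants therefore demonstrate that the machinery is correct and can learn
organ geometry at realistic imbalance — not that the reported IoUs
transfer to field scans.

## Numerical choices and problem sizes

* Half-open voxel cells with max-corner clamping; exact integer keys for
  all site lookups.
* Argmax decoding breaks ties toward the lowest class index; majority-vote
  voxel labels break ties toward the smaller class id.
* Softmax and cross entropy are computed with max-shifted exponentials;
  probabilities are floored at 1e-12 inside the log.
* The Lovász-softmax gradient treats the Jaccard-extension coefficients as
  constants (they are piecewise constant in the errors), the standard
  subgradient choice.
* Normalisation epsilon 1e-5; Adam epsilon 1e-8, betas 0.9/0.999.
* The test and acceptance harnesses run at desk scale by design: a
  20 000-point plant for the overfit check (small 16/32 configuration,
  resolution 64, at most 300 Adam steps) and ten 6 000-point plants
  (eight train, two held out, 25 epochs) for the generalisation check.
  These sizes were chosen once as the smallest configurations that exercise
  every component — multi-stage U-Net, fusion, imbalance handling — while
  keeping the full suite comfortably reproducible on a single CPU.

## Known limitations

* Pure-R execution: throughput is adequate for desk-scale clouds
  (~10⁴–10⁵ points) but training on million-point scans needs the same
  architecture on an accelerator framework.
* No instance segmentation: per-leaf instance ids are deliberately
  collapsed to one leaf class.
* No test-time augmentation, no learning-rate schedule, no multi-plant
  scenes, and no streaming of clouds larger than memory.
* Batches are processed cloud-by-cloud with gradient averaging; batch
  normalisation statistics are therefore per-cloud, which is the
  deterministic choice but differs from cross-cloud batch statistics.
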