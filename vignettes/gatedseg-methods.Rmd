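---
title: "Attention-gated 3D segmentation networks: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated 3D segmentation networks: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem and the model

`gatedseg` implements a complete methodology for voxel-wise organ and
tumor segmentation in abdominal CT: a 3D encoder–decoder convolutional
network extended with **additive attention gates** (AG) on its topmost
skip connections and **deep supervision** (DSV) heads on its topmost
decoder levels, together with the preprocessing, patch-based training and
Gaussian-weighted sliding-window inference that such networks require.

Two topology variants are provided:

* **UNet** — max-pooling in the encoder, trilinear upsampling in the
  decoder;
* **VNet** — fully convolutional: non-overlapping strided convolutions
  (kernel = stride = 2 on active axes) replace pooling, transposed
  convolutions replace interpolation.  The kernel-2/stride-2 choice
  follows the original fully convolutional volumetric design; it keeps
  down/up transitions parameterized but free of checkerboard overlap.

Each encoder (*context*) and decoder (*localization*) module is two
blocks of `conv(3×3×3) → dropout → instance norm → leaky ReLU`.  Feature
maps start at `base_features` (default 30) and double at each level, up
to a cap of 320.  An axis whose entry in `levels_per_axis` is exhausted
is no longer downsampled at deeper levels, which handles the anisotropic
patch shapes of the shipped per-task presets (e.g. kidney full
resolution: patch 160×160×48, levels 5,5,3).

### Attention gates

A gate compares skip features $x^l$ ($F_l$ channels, fine grid) against
the gating signal $g$ — the decoder features of the next-coarser level
($F_g$ channels).  On the coarse grid it computes

$$q = \psi^\top\,\mathrm{ReLU}(W_x^\top x^l_\downarrow + W_g^\top g + b_g) + b_\psi,
\qquad \alpha = \sigma(q) \in [0,1],$$

where every linear map is a 1×1×1 convolution and $x^l_\downarrow$ is
$x^l$ brought to $g$'s grid by folding a stride-2 subsampling into
$W_x$.  The coefficient map is upsampled trilinearly to the fine grid
and multiplies every channel of $x^l$.  One map is shared across classes
and channels; gates sit on the two topmost levels (`ag_levels = 2`),
where the coefficients resolve organ-scale structure.  The intermediate
width is $F_{int} = \lfloor F_l/2\rfloor$.

**Pass-through initialization.**  Freshly built gates must not attenuate
anything, otherwise early training starves.  Setting the $\psi$ weights
to zero and $b_\psi = 10$ gives $\alpha = \sigma(10) \approx 0.99995$
everywhere while $W_x, W_g$ (He-normal) keep the gate trainable: the
zero weights lie on a saddle that the $W$-paths escape after the first
updates.

### Deep supervision

1×1×1 heads produce secondary segmentation maps at the three topmost
decoder levels.  The coarsest map is upsampled (trilinearly — the 3D
reading of the cited bilinear step) to the next level's grid, added, and
so on until full resolution; the level-0 head terminates the chain and
*is* the network output.  No per-level auxiliary losses are used: the
loss is applied once to the combined full-resolution output, and the
lower heads contribute gradient through the summation chain.  The sum is
unweighted (no weighting is stated anywhere for this chain).

### Objective

Training minimizes the sum of a soft dice loss and cross-entropy on the
softmax output $u$ against the one-hot target $v$:

$$L_{dice} = -\frac{2}{|C|}\sum_{c\in C}
  \frac{\sum_i u_{ic}v_{ic}}{\sum_i u_{ic} + \sum_i v_{ic} + \varepsilon},
\qquad
L_{CE} = -\frac{1}{|I|}\sum_i \sum_c v_{ic}\log u_{ic}.$$

Choices worth noting:

* $\varepsilon = 10^{-5}$ guards classes absent from both maps (0/0);
* the printed cross-entropy is a plain sum; we divide by the voxel count
  so the loss magnitude is patch-size invariant (configurable via
  `reduction = "sum"`);
* the background class is included in the dice average (the class sum
  carries no exclusion), configurable via `include_background`;
* probabilities are clamped at $10^{-7}$ before the log.

The published dice formula prints a union in its numerator; a union
would score disjoint masks at 200, so the standard intersection form
$D = 2|U\cap V|/(|U|+|V|)\cdot 100$ is implemented (the union is treated
as a typo).  Composite dice is the unweighted mean over foreground
classes; reporting uses decimal half-up rounding so values recomputed
from printed per-class scores match their printed composites
(e.g. `mean(81.22, 52.99) → 67.11`).

### Optimization

Adam (`lr = 3e-5`, $l_2$ weight decay `3e-5`), batch size 2, He-normal
initialization, gates re-initialized pass-through.  An epoch is one pass
worth of iterations over the training cases.  Whenever the exponential
moving average of the training loss (EMA, $\beta = 0.9$; initialized to
the first epoch's loss) fails to improve by at least $10^{-5}$ for 30
consecutive epochs, the learning rate is multiplied by 0.2 and the
patience counter resets (a reset, not a sliding window — the
conservative reading).  Training stops when the rate drops below
$10^{-6}$ or after 1000 epochs.  The retained checkpoint is the epoch
with the best loss EMA; training loss is monitored, not validation loss.

### Sampling and augmentation

Patches are cut on the fly; at least one patch per batch is forced to
contain foreground — it is centred on a uniformly drawn foreground voxel
(the stronger reading of "contains at least one foreground class"),
clipped to bounds.  Augmentations (rotation ±30° p=0.2, isotropic scale
0.85–1.25 p=0.2, elastic deformation with Gaussian-smoothed displacement
fields α∈[0,200], σ∈[9,13] p=0.2, gamma 0.7–1.5 p=0.3, per-axis
mirroring p=0.5) follow the conventional defaults of on-the-fly 3D
augmentation frameworks, since no values are published.  Spatial
transforms use trilinear interpolation for images and nearest neighbour
for labels; out-of-bounds regions take the patch minimum (image) or
background (labels).

### Preprocessing

A dataset *fingerprint* drives preprocessing: median voxel spacing,
median resampled shape, and the 0.5/99.5 percentiles, mean, and
(population) standard deviation of intensities inside the segmentation
masks, pooled over all non-zero labels and all cases.  Images are
resampled to the median spacing with separable natural-cubic
(third-order) spline interpolation, masks with nearest neighbour; the
output grid is `round(shape × spacing / target)` per axis with
half-voxel centre alignment.  Intensities are clipped to the percentile
window and z-scored.  The low-resolution variant doubles the spacing
isotropically until the median shape holds fewer than four times the
voxels of one patch; the published low-resolution median shapes are not
exact halvings of the full-resolution ones (the original anisotropy
handling is unstated), so the shipped presets carry the published values
verbatim and the halving rule applies to user datasets only.  Percentile
interpolation is linear between order statistics.

### Inference

Prediction is patch-wise with half-patch overlap.  Aggregation weights
each voxel by a separable Gaussian with σ = patch/8 per axis, maximum 1
at the patch centre.  A strict zero at the border would leave
volume-corner voxels with an all-zero weight stack, so the weights are
floored at $10^{-6}$ — the one deliberate deviation from the printed
description, affecting only voxels covered by a single patch border.
Test-time augmentation averages the softmax over all 8 mirror
reflections in probability space (the merge space is unstated; averaging
probabilities keeps the result on the simplex).  Full- and
low-resolution softmax volumes are ensembled by trilinear resampling of
the low-resolution map, unweighted averaging, then argmax, with ties
broken toward the lowest class index; the final mask is brought back to
the case's original geometry by nearest neighbour before evaluation.

## The phantom generator

Real CT training data for these tasks is large and external, so the
package ships a deterministic phantom generator that reproduces the
*statistical structure* the method depends on: a large smooth organ
(ellipsoid at random pose, semi-axes 8–13 mm) containing a small tumor
sphere (radius 3–5 mm, verified voxel-wise to lie strictly inside the
organ), heavy class imbalance (background ≫ organ ≫ tumor; foreground
under 10% of voxels, so the foreground-guaranteed sampler and the dice
term matter), overlapping class intensity distributions (means 40/65/90
HU-like against a noise SD of 25 — adjacent classes separated by about
one noise SD, so voxel-wise thresholding fails and spatial context is
required), partial-volume blur at boundaries (0.8 mm Gaussian), and
optional anisotropic spacing.  These defaults were fixed once as a
realistic soft-tissue contrast regime.

At the study's 300-step budget the attention gates remain close to
their saturated pass-through initialization (coefficients near 1
everywhere); the organ-localized attention patterns reported for fully
trained models emerge only over far longer schedules.  The exported
coefficient maps are therefore validated structurally (bounds, count,
geometry) rather than semantically at this scale.

What phantoms do **not** emulate: true CT texture and artifacts,
multiple organs, heterogeneous tumor appearance, inter-scanner protocol
variation, or anatomical shape variability.  Passing the phantom study
therefore demonstrates that the pipeline's machinery — preprocessing,
gating, deep supervision, the loss, the optimizer, stitching — is
implemented coherently and can learn a spatial segmentation under
class imbalance; it does not certify clinical-grade accuracy on real
scans.

## Scaled-down study sizes

The end-to-end study trains the scaled-down configuration
(`tiny_spec()`: V-Net-AG-DSV, 8 base features, levels (3,3,3), 32³
patches, batch 2) for 50 epochs × 6 iterations = 300 gradient steps on
12 phantoms and evaluates composite dice on those cases and on 6
held-out phantoms, against an identically budgeted plain V-Net.  These
sizes were chosen so a study completes in minutes on one CPU while still
exercising every component at realistic class imbalance.  The study uses
Adam at `lr = 1e-3` rather than the published `3e-5`: that rate is
calibrated for roughly 10⁵ gradient steps on real CT, where a 300-step
schedule cannot move He-scale weights appreciably; 1e-3 is the
conventional Adam rate for short schedules on small networks.
Augmentation is disabled in the study (every phantom is already a fresh
draw from the generating distribution, so the overfitting pressure that
augmentation counteracts is absent at this scale).

## Numerical notes

* The computational core is a small reverse-mode autodiff tape over
  BLAS-backed kernels.  The 3×3×3 convolutions run their GEMMs in single
  precision (the rest of the pipeline is double): the ~10⁻⁷ relative
  rounding this introduces is far below optimization noise, and it
  roughly doubles throughput on one CPU.  Gradient tests account for
  this with matched finite-difference steps.
* Instance normalization uses eps 10⁻⁵ and per-sample, per-channel
  statistics — also at inference, where each tile is normalized by its
  own statistics (the standard behaviour of instance norm).
* Dropout masks derive from a xorshift stream seeded from R's RNG, so
  results are reproducible under `set.seed` at a fraction of the cost of
  drawing per-element uniforms from R.
* Degenerate inputs have defined behaviour: a dataset with zero
  foreground refuses to fingerprint; a zero foreground SD refuses to
  normalize; precision with no positive predictions reports 0 (flagged);
  dice with both masks empty reports 100 (flagged); an all-background
  case degrades foreground-forcing to a warning instead of failing a
  whole training run.
* The "downsample until feature maps reach size 8" guideline conflicts
  with several published patch/level combinations (e.g. axis 96 with 5
  levels), so the per-axis level counts of the plan are authoritative
  and the size-8 rule is only an advisory message.

## Known limitations

* No connected-component post-processing (mentioned in the source
  methodology only as future work).
* 2D networks, residual variants and cascade models are out of scope.
* Training at the published full scale (patch 160×160×48, 1000 epochs)
  is computationally out of reach for a CPU-only R implementation; the
  package targets methodological fidelity and desk-scale studies, not
  GPU-scale training throughput.
* Per-class attention maps (the class-indexed reading of the gating
  equations) are not implemented; one map is shared, matching the
  figures of the source design.
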