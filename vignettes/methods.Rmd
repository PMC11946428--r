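---
title: "Cascaded liver and tumor segmentation: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded liver and tumor segmentation: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the approach

Liver tumors on abdominal CT are small, low-contrast targets embedded in an
organ whose own boundary is ambiguous against neighboring soft tissue.
`liverseg` implements a two-stage (coarse-to-fine) volumetric segmentation
cascade: a first network localizes and segments the liver on the
preprocessed volume; a second, independently trained network segments
tumors only inside the liver's region of interest (ROI). Restricting stage
two to the organ removes most of the background that drives false
positives, which is the main argument for cascades over single-stage
multi-class segmentation.

Both stages use the same backbone: a four-level 3D U-Net (encoder,
bottleneck, decoder, channel-concatenating skip connections) whose stage
units can be switched between plain convolutions and the two specialized
blocks described below, giving four ablation variants (`unet`,
`msca-unet`, `elanres-unet`, `elanres-msca-unet`).

## Preprocessing and its inversion

1. **Body mask.** Threshold at −300 HU (air is ≈ −1000 HU), binary closing
   with a 3-voxel ball, slice-wise hole filling, largest 26-connected
   component. The threshold and structuring element are conventional CT
   body-extraction choices and are exposed as arguments.
2. **Crop** to the body bounding box plus a 5-voxel margin.
3. **In-plane downsampling** by a fixed factor 0.5 (x and y halved, z
   untouched), trilinear for intensities and nearest-neighbor for labels.
   We interpret the resolution reduction as matrix halving rather than
   resampling to a fixed physical spacing: with native in-plane spacings
   varying between cases, both readings exist, and only the fixed factor
   makes the preprocessing geometry exactly invertible case by case.
4. **Windowing** to [−200, 200] HU mapped affinely to [0, 1]. A
   normalization factor of 200 applied after clipping would instead give
   [−1, 1]; we honor the stated unit output range and keep the signed
   variant behind `window_normalize(mode = "signed")`.

Every crop/downsampling is recorded in a `preprocess_record`, and
`restore_to_original()` inverts it exactly (nearest-neighbor in-plane
upsampling, paste into the crop box), so predictions are always reported
on the original grid. Coordinates are 0-based with half-open crop boxes in
(x, y, z) NIfTI storage order; this convention is what makes the record
invertible and is asserted by round-trip tests.

## The backbone and the two specialized blocks

Each resolution level holds a *stage* of two units. The lead unit changes
the channel count; the refinement unit preserves it. Downsampling is a
stride-2 3×3×3 convolution; upsampling is trilinear interpolation followed
by a 3×3×3 convolution. All trunk convolutions are bias-free and followed
by batch normalization and ReLU. Four 1×1×1 heads produce pre-sigmoid
logits at the bottleneck and the three decoder scales; every head is
trilinearly upsampled to the input grid so all four losses compare against
full-resolution labels (no label-downsampling scheme is needed).

**ELANRes block** (lead unit when enabled). A 1×1 stem widens the input to
`split + hidden` channels; the `split` channels pass through untouched
while the `hidden` channels run through three sequential
*re-parameterizable units*. Each unit sums two parallel 3×3×3 convolution
branches, a 1×1×1 branch and the identity, then applies one batch norm and
ReLU. The pass-through and the three unit outputs are concatenated and
fused by a 1×1 convolution; a 1×1-projected residual of the block input is
added before the output activation.

Because the parallel branches are linear and the normalization follows the
sum, every unit collapses at deployment into a single 3×3×3 convolution:
`merge_branches()` zero-pads the 1×1×1 kernel and encodes the identity as
a centered delta kernel before summing, and `fuse_norm()` folds the frozen
normalization statistics into the merged kernel and bias. The collapse is
exact linear algebra; only accumulation order differs, so we assert
equivalence at 1e−5 per unit and 1e−4 across the full network in the
engine's single-precision arithmetic. Merging is applied only across the
parallel branches of a unit — never across the concatenation/fusion
structure or a nonlinearity, where it would not be exact.

**MSCA block** (encoder refinement unit when enabled). Volumetric features
are folded slice-wise (`volume_to_slices()`) so that 2D convolutions do
the work. The block normalizes its input (instance-style, per slice and
channel), sums four depthwise multi-scale kernels — 5×5 and the separable
strip pairs 1×7/7×1, 1×11/11×1, 1×21/21×1 — mixes channels with a 1×1
convolution, and multiplies the result element-wise with the normalized
features (the attention step). After a residual add, a second normalization
and an MLP (1×1 expansion, depthwise 3×3, GELU, 1×1 reduction) with its own
residual complete the block. Strip pairs are tested against their dense
outer-product equivalents; the attention path and MLP use GELU while the
trunk uses ReLU, following the published ancestry of each component.

### Width calibration

The reference description of this architecture family reports no channel
widths; its only architectural ground truth is the set of four
trainable-parameter counts of the ablation variants
(13,063,192 / 11,449,720 / 14,738,072 / 13,124,600). Two structural facts
follow directly from those numbers: the attention variant is *cheaper*
than the baseline, so the MSCA block must replace (not follow) a
convolution unit; and the two substitution deltas are exactly additive, so
the two block types must substitute disjoint units. We therefore replace
the second (refinement) conv of the four encoder stages with MSCA and the
lead conv of all seven stages with ELANRes.

The remaining free integers — stage channels, the per-stage MSCA MLP
hidden widths and the per-stage ELANRes hidden/pass-through widths — were
fixed once by an enumeration that solves the three count equations
exactly (`tools/calibrate_widths.R`): stage channels (44, 55, 221, 263),
MLP hiddens (267, 377, 1321, 1577) (≈ 6× expansion), ELANRes hiddens
≈ 0.45× and splits ≈ 0.47× of each stage's output width. All four counts
reproduce exactly and are asserted in the acceptance suite. Smaller
configurations (for tests and phantoms) derive block widths from the same
ratios.

## Losses and deep supervision

Soft counts over sigmoid probabilities define the region losses
(`Intersection = Σ p·y`, `FP = Σ p·(1−y)`, `FN = Σ (1−p)·y`), which keeps
them differentiable and reduces to the set-theoretic definitions on hard
masks:

* Dice loss `1 − 2I/(Σp + Σy + ε)`, ε = 1e−5. The denominator is the sum
  of the two set sizes (as in the Dice index definition), not the
  cardinality of the set union.
* Tversky loss `1 − I/(I + 0.3·FP + 0.7·FN + ε)`, weighting false
  negatives more heavily for small-lesion sensitivity.
* Voxel-mean binary cross-entropy with probabilities clamped at 1e−7.
* `hybrid1 = (1−λ)·Dice + λ·BCE` and `hybrid2 = (1−λ)·Tversky + λ·BCE`
  with λ = 0.5. `hybrid1` is the default training loss.

The four heads share the configured loss. The total is
`loss3 + α·(loss0 + loss1 + loss2)` with the auxiliary weight starting at
α = 0.4 and decaying by the factor 0.8 once per period. The decay period
is not quantified by the source beyond "periodic"; we align it with the
30-epoch learning-rate period, the only periodicity stated. No floor is
applied to α.

## Training

Adam with initial learning rate 1e−4 reduced by 20% every 30 epochs
(`lr_at_epoch()` is the closed form). Cases are split 3:1 into training
and validation deterministically per seed. One foreground-oversampled
patch (fraction 0.5) is drawn per optimization step; gradients therefore
come from one patch at a time, and the region losses are computed per
patch — the engine operates on single dense arrays rather than batched
tensors, and per-patch region losses are the standard alternative to
batch-pooled counts. Stage-2 training crops every case to its
ground-truth liver ROI first, so tumor training consumes only voxels
inside the liver region. The best-validation-Dice weights are kept when a
validation set is supplied. Seeds cover the split, sampling, and
initialization; two runs with the same seed produce identical loss curves.

## Cascaded inference

`two_stage_predict()` chains: preprocessing → stage-1 sliding-window
prediction → threshold 0.5 → largest 26-connected component → ROI with a
10-voxel margin → stage-2 prediction inside the ROI → threshold 0.5 →
clamp tumors to the liver mask → restore both masks to the original grid
→ compose the {0, 1, 2} label map. The threshold, margin, connectivity and
patch geometry are arguments; 0.5 is the natural operating point of a
sigmoid head, 26-connectivity avoids splitting thin liver bridges, and
the margin tolerates moderate stage-1 under-segmentation. The
largest-component rule is applied to the liver only — tumors are
legitimately multi-focal. The containment clamp turns the cascade's
"tumors lie inside the liver" assumption into an enforced invariant,
asserted on every result.

Sliding-window prediction tiles patches at 50% overlap, averages sigmoid
probabilities uniformly, zero-pads volumes smaller than one patch and
crops back, and is deterministic for fixed weights.

## Evaluation suite

Per case: Dice, average symmetric surface distance (ASD), relative volume
difference, precision and recall (all five for tumors; Dice and ASD for
the liver). Surfaces are mask voxels with at least one 6-neighbor outside
the mask (the grid border counts as outside); distances are Euclidean
between voxel centers in mm with anisotropic spacing. ASD is computed with
an exact anisotropic Euclidean distance transform
(lower-envelope/parabola method), which the tests pin to a brute-force
all-pairs oracle at 1e−9 — any accelerated implementation must match the
oracle, not approximately but exactly up to round-off. Degenerate inputs
are explicit: Dice of two empty masks is 1, ASD of an empty mask is an
error (reported as NA per case and flagged), RVD requires a nonempty
prediction.

Lesion sizes are Feret diameters (maximum pairwise surface-point distance,
in mm) of 26-connected components of the ground-truth tumor mask; the
Feret diameter is parameter-free, unlike a fitted-ellipsoid axis. The
stratified report partitions cases at Dice ≥ 0.6 (boundary cases in the
high-performance group) and averages lesion sizes per group.

ASD is reported in mm; a voxel-unit reading can be obtained by dividing by
the mean spacing, and the per-case tables carry the spacing so either
convention can be recovered.

## The phantom generator

Phantoms stand in for abdominal CT during development and testing: a body
ellipsoid (≈ 0 HU) in air (≈ −1000 HU), a liver-like ellipsoid (60 HU)
inside the body, and 1–3 spherical tumors (30 HU) strictly inside the
liver (a `boundary_tumors` variant lets spheres cross the liver surface,
exercising the containment clamp). Gaussian noise (sd 10 HU) gives a
3σ lesion contrast — learnable by a small network in minutes yet not
trivially thresholdable. All region intensities sit inside the
[−200, 200] HU window so preprocessing cannot clip away signal. Labels
are exact by construction, so metric computations on phantoms have
analytic oracles (ellipsoid volume 4/3·π·abc, sphere Feret diameter 2r).

The default grid is 128×128×32 at (1.5, 1.5, 2.5) mm: after body cropping
and in-plane halving a phantom fits a single 64×64×32 training patch
almost exactly, so desk-scale training sees the whole anatomy each step.
What phantoms do *not* emulate: soft-tissue texture, vessels, adjacent
organs of similar intensity, breathing motion, or annotation noise.
Passing the phantom cascade therefore demonstrates that the pipeline's
machinery (preprocessing geometry, optimization, cascading, restoration,
metrics) is correct — not that the model reaches clinical-grade accuracy
on real CT, which requires full-scale training on LiTS-style data.

## Desk-scale problem sizes

The self-contained end-to-end check trains both cascade stages at desk
scale: 10 phantoms (8 training, 2 held out), the plain `unet` variant at
widths (8, 16, 32, 64), one 64×64×32 patch per step, 150 Adam steps per
stage at learning rate 1e−3, auxiliary weight decayed on the 5-epoch
period implied by 30-step epochs. These sizes are the package's chosen
desk-scale study conditions: the cascade criterion (held-out liver
Dice ≥ 0.85, tumor Dice ≥ 0.5) is comfortably met by the plain variant
(measured across seeds: liver ≈ 0.94–0.96, tumor ≈ 0.81–0.84),
whose optimization is the least forgiving of the four — the specialized
blocks are exercised by their own equivalence and gradient tests. At
desk scale the learning rate is raised from the full-scale 1e−4 to 1e−3:
with ~10^2 updates rather than ~10^4, the full-scale rate would leave the
random initialization essentially unchanged.

## Numerical choices

* Working precision: forward passes accumulate in double; convolution
  *backward* passes accumulate in single precision (mixed precision —
  gradient noise from float32 is far below optimization noise). The
  deployment-equivalence tolerances (1e−5 per unit, 1e−4 whole network)
  are stated for single-precision accumulation and hold with large
  margin under the double forward.
* Normalization: batch norm uses ε = 1e−5 and momentum 0.1 running
  statistics; deployment folds the running statistics, matching
  evaluation-mode outputs.
* Probability clamp 1e−7 inside logarithms; the BCE gradient uses the
  exact logit form `(p − y)/N`, which needs no clamp.
* Trilinear resizing uses the half-voxel-center convention
  (`src = (dst + 0.5)·scale − 0.5`, clamped), implemented separably per
  axis; its backward is the exact adjoint, asserted by an inner-product
  identity.
* He initialization scaled by fan-in throughout; seeds are the user's.
* Ties in the largest-component rule resolve to the first-labeled
  component (deterministic scan order).

## Known limitations

* The native engine is CPU-only and single-sample; full-scale LiTS
  training (hundreds of epochs at 13M parameters) is out of its practical
  reach — the full-scale configuration is provided and exact, but the
  published LiTS/3Dircadb scores are not reproducible at desk scale and
  are not claimed by any test.
* Normalization statistics come from single-patch passes; very small
  patches give noisy statistics.
* The attention block's slice folding assumes the z axis is the slice
  axis, as in LiTS-style axial CT.
* `read_case()` ingests NIfTI only; DICOM series must be converted
  upstream.
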