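---
title: "Methods: an aggregation-and-attention network for brain tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an aggregation-and-attention network for brain tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gliomas appear on multi-parametric brain MRI as nested tissue compartments:
peritumoral edema surrounds a tumor core, which in turn contains a
GD-enhancing rim and a necrotic/non-enhancing center. Clinical evaluation
follows the BraTS convention and scores three *nested* regions derived from
the voxel labels {0 background, 1 necrotic/non-enhancing (NCR/NET),
2 edema (ED), 4 enhancing (ET)}:

* whole tumor **WT** = {1, 2, 4},
* core tumor **CT** = {1, 4},
* enhancing tumor **ET** = {4},

so ET &sube; CT &sube; WT by construction. Each region is segmented as its
own binary channel and scored with Dice, precision, sensitivity and the
Hausdorff distance. Color-key descriptions of these regions are sometimes
given inconsistently; this package follows the standard BraTS hierarchy
above and keeps the mapping in one function (`brats_region_map()`) so an
alternative mapping is a single switch.

## The network

The model is a U-Net-shaped encoder-decoder over 160 x 160 slices with four
stacked modality channels (T1, T2, T1ce, FLAIR), with four bespoke block
types.

**EDS (enhanced down-sampling) encoder blocks.** Each stage applies two
3 x 3 conv + batch-norm + ReLU layers (activations G1, then G2) plus a
parallel 1 x 1 conv-BN-ReLU residual branch R, and pools the sum:
`h = maxpool(G2 + R)`. A fused supervision feature
`A = concat(conv(G1), conv(G2))` (each half-width, so A keeps the stage
width) exposes both low-level detail and higher-level shape; A feeds the
skip connection and a region-logit head that is bilinearly upsampled to
full resolution for deep supervision.

A note on widths: a halving-width encoder would be incompatible with the
U-Net backbone this design builds on, so the package follows the U-Net
convention — widths double each stage from `base_channels` (default 32).
The residual branch uses a 1 x 1 kernel, the only choice that matches the
addition against the double-conv output.

**MSC (multi-scale connection) skips.** Instead of identity skips, A passes
through four parallel branches — a 1 x 1 conv and three 3 x 3 dilated convs
with (padding, dilation) of (6,6), (12,12), (18,18) — concatenated and
fused back to the stage width by a 1 x 1 conv-BN-ReLU. Padding equal to
dilation preserves the spatial size at every stage. The `msc_positions`
switch reproduces the position-ablation grid (any subset of stages 1-4;
disabled positions fall back to identity skips).

**DAF (dual-attention fusion) bottleneck.** Two 3 x 3 conv-BN-ReLU layers
produce the bottleneck feature, which two attention heads re-weight:

* *Positional attention*: 1 x 1 convs project to query/key maps at reduced
  width C/8 (the reduction conventional in this attention family) and a
  value map at full width; the softmax-normalized
  pixel-pair affinity `S[j, i]` re-weights values, and the output is
  `alpha * (value-weighted sum) + input`.
* *Channel attention*: channel-pair affinities are computed directly from
  the reshaped feature map, deliberately without any convolution, and the
  analogous softmax-weighted sum is scaled by `beta` and added to the
  input. Because no convolution is involved, permuting input channels
  permutes the output channels identically, which the tests check.

`alpha` and `beta` are learnable scalars initialized to 0, so both heads
start as exact identities — a property pinned by tests. The fusion variants
mirror the ablation: DAF1 (the default) fuses `conv(PA + CA)`; DAF2 adds
each attention output to a parallel 1 x 1 branch and concatenates; DAF3
concatenates both fusion paths. DAF2 and DAF3 are looser designs whose
internal wiring admits several readings; this package implements the
documented interpretations above behind the `daf_variant` switch, while
DAF1 is fully pinned by the attention equations.

**US (up-sampling) decoder layers.** Each stage concatenates the previous
decoder feature with the same-level MSC feature and applies the EDS
residual double convolution with the pooling slot replaced by 2x bilinear
upsampling followed by a 1 x 1 conv (bilinear is this package's choice of
upsampling operator; transposed convolution is the obvious alternative).
The deepest decoder input is the DAF output upsampled to the deepest skip
resolution; the last stage is already at full resolution and applies no
trailing upsampling. Each stage carries its own supervision head.

The final 1 x 1 head emits three region logits per pixel; sigmoids and a
0.5 threshold produce the WT/CT/ET masks. Because the three sigmoid
channels are independent, predicted masks need not nest; an optional
repair flag (off by default, as repair is not part of the trained model)
enforces ET &sube; CT &sube; WT by intersection at inference.

## Loss

Each head h is scored with `L(h) = 0.5 * BCE + DiceLoss` where BCE is the
pixel-mean binary cross-entropy (probabilities clamped at 1e-7 for log
safety) and `DiceLoss = 1 - 2*sum(T*P) / (sum(T^2) + sum(P^2) + 1e-5)`,
computed per region channel and per sample, then averaged. The Dice
*coefficient* (maximized at perfect overlap) cannot itself serve as a
minimized loss; the package uses the universal `1 - coefficient`
orientation.

The total is

```
L_total = lambda1 * (L_down + L_up) + lambda2 * L_dual + L_result
```

with `lambda1 = 0.4`, `lambda2 = 0.2`; `L_down`/`L_up` average the four
encoder/decoder heads (mean rather than sum, so the lambdas do not depend
on the head count), `L_dual` is the bottleneck head and `L_result` the
final head. The decomposition identity is asserted to 1e-7 in the tests.

## Preprocessing

Volumes are z-score normalized to mean 0 / sd 1 *over their nonzero (brain)
support* — statistics over all voxels would be dominated by the zero
background and compress the brain contrast — with background kept exactly
zero; normalization precedes the center crop, so the support statistics
come from the full volume.
In-plane 240 x 240 is center-cropped to 160 x 160 (offsets (40, 40)), all
155 axial planes are kept, and the four modality planes of each Z index are
stacked into one 160 x 160 x 4 sample. Train/validation splitting is done
at the case level, so no subject contributes slices to both sides.

## Evaluation metrics

Per slice and region: Dice `2TP/(2TP+FP+FN)`, precision `TP/(TP+FP)`,
sensitivity `TP/(TP+FN)`, and the symmetric Hausdorff distance between
mask boundaries (a foreground pixel is boundary if any 4-neighbor,
including off-image, is background; distances are Euclidean in pixel
units). Degenerate denominators follow the convention that a slice where
prediction and truth are both empty scores 1 (and Hausdorff 0), so
tumor-free slices do not produce NaNs; one-empty Hausdorff returns the
image diagonal as a sentinel. The plain (not 95th-percentile) Hausdorff is
used, per the min/max definition. Published tables in this problem family
report Hausdorff values around 1-2, consistent with some normalization
that is not described; pixel-unit distances on 160 x 160 masks live on a
different scale, and no attempt is made to match that reporting scale.

## The phantom generator

Real BraTS data cannot be redistributed, so the package generates
multi-modal phantoms: a circular "brain" disc (radius 0.45 of the image)
on a zero background, with three concentric ellipses (axis ratio 0.85) for
edema/enhancing/necrotic compartments at default radii 0.30/0.18/0.08 of
the image size, labeled 2/4/1. Channel intensities come from a 4 x 5
tissue-contrast table chosen once to mimic the clinical pattern — FLAIR
bright in edema, T1ce bright in the enhancing rim and dark in the necrotic
core — plus i.i.d. Gaussian noise (sd 0.03). Dataset generation jitters
tumor position (within the brain disc) and radii (+-10%) and gives each
slice its own noise stream, all reproducible from one seed. The 3-D writer
stacks slices whose radii follow an ellipsoidal Z profile and emits the
BraTS on-disk layout so the whole NIfTI reading/preprocessing path is
exercised.

What the phantom deliberately does not emulate: realistic tumor shapes and
infiltrative margins, Rician MRI noise, bias fields, anatomy, or 3-D
continuity beyond the radius profile. Passing tests therefore demonstrate
that the architecture, gradients, preprocessing and metrics are correct
and that the network can fit intensity-separable nested structures; they
say nothing about segmentation accuracy on clinical images.

## Numerical choices

* All arithmetic is double precision; convolution/pooling/upsampling and
  batch-norm kernels are compiled, with gradients verified against central
  finite differences to 1e-5 relative error.
* Softmax rows are shifted by their max before exponentiation (exact).
* Batch norm uses population batch statistics with eps 1e-5 and running
  statistics (momentum 0.1) for eval mode.
* Bilinear upsampling uses half-pixel centers with border clamping.
* Region-logit heads initialize weights as He-normal and biases at -2
  (foreground prior about 0.12). Zero-bias heads start near p = 0.5
  everywhere, and the Dice term then rewards flooding the mask with
  positives before carving it back, which makes early training slow and
  seed-sensitive; starting at the background prior removes that phase.
* Attention scales alpha/beta start at 0 (identity), so the attention
  heads perturb a working encoder-decoder rather than scrambling it.
* Ties in max pooling take the first element in column order;
  `maxpool` requires even spatial dims, which the 160/80/40/20 pyramid
  guarantees.

## Training

Adam (lr 3e-4, beta 0.9/0.999), batch size 16, up to 100 epochs with
early stopping after 20 epochs without improvement of the monitored mean
validation Dice over WT/CT/ET (a 100-step budget is read as 100 epochs,
consistent with a patience of 20 on a validation trend, and mean Dice is
the natural monitor for this loss). The best-monitor checkpoint is kept.
No data augmentation is used. Everything is seeded:
(model seed, config seed) fix initialization and data order, and two runs
agree on epoch-0 losses exactly, which the tests assert.

The test suite and acceptance script use a scaled-down smoke
configuration chosen once as this package's standard check: 8 phantom
slices at 160 x 160, base width 8, Adam lr 3e-4, batch 2, 40 epochs (160
optimizer steps). All seeds tried reach mean training Dice well above 0.9
within those steps; the full-width (base 32) configuration is exercised
for shape contracts only, since training it is a GPU-scale undertaking.

## Known limitations

* 2-D slice-wise segmentation only; no 3-D convolutions or cascades.
* The overfit check certifies learnability on phantoms, not clinical
  accuracy; headline benchmark numbers require the real BraTS data and
  GPU-scale training, both out of scope here.
* DAF2/DAF3 are documented interpretations of one-sentence descriptions.
* Hausdorff is reported in pixel units (see above).
* Training throughput targets small CPU experiments; the implementation
  is single-threaded apart from BLAS.
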