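---
title: "Methods: scale and feature aggregation for retinal vessel segmentation"
author: "sfanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scale and feature aggregation for retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Retinal vessel segmentation assigns every pixel of a fundus photograph a
probability of belonging to the vasculature, evaluated only inside the
circular field of view (FOV) that the camera actually images. The package
implements a U-shaped encoder–decoder convolutional network built from a
`Conv3x3 + BatchNorm + ReLU` unit, with four 2×2 max-pooling stages, and
three feature-aggregation blocks that can be enabled independently:

* **RASF** (residual atrous spatial feature aggregation) at the bottleneck:
  three parallel dilated 3×3 convolution units with rates 1, 3 and 5 give
  multiscale maps $F_1, F_2, F_3$; the sum path $F_{12} = F_1 \oplus F_2$ is
  fused by a 3×3 convolution with ReLU and squeeze–excitation channel
  attention whose gate multiplies $F_1$; the product path
  $F_{23} = F_2 \otimes F_3$ passes a per-pixel channel softmax and
  re-multiplies $F_3$; both paths are concatenated, reduced back to the
  input width by a 3×3 convolution, and added to the input through a
  residual connection.
* **AFF** (attentional feature fusion) replaces each vanilla skip
  connection: the shallow feature *before* the level's convolutions
  (`low1`, i.e. the pooled tensor entering the level — the raw input at the
  first level) is projected by a convolution unit, globally pooled, and the
  resulting per-channel weights gate the post-convolution shallow feature
  (`low2`); the gated map is L2-normalised across channels per pixel and
  concatenated with `low2` and with the transpose-convolution upsampled
  decoder feature.
* **MPF** (multi-path fusion) forms the head: the three finest decoder
  stages are bilinearly upsampled to full resolution and projected to a
  common width; the two coarser paths are multiplied, channel-softmaxed,
  globally pooled and rectified into a gate that modulates the finest path,
  which a 1×1 convolution and sigmoid turn into per-pixel probabilities.

Training minimises the mean binary cross-entropy
$-\,\mathrm{mean}\,[\,y\log p + (1-y)\log(1-p)\,]$ with Adam. The five
ablation variants (`baseline`, `rasf`, `aff`, `rasf_aff`, `full`) switch the
blocks on cumulatively; the baseline is a plain U-shaped network with
transpose-convolution upsampling and concatenation skips.

## Design choices where the architecture description is open

Several wiring details are shown only pictorially in diagrams of this
architecture family, so the package fixes them explicitly:

* **Softmax axis.** The softmax inside RASF and MPF acts across channels at
  each spatial position: its output multiplies a same-shaped map
  elementwise, and the channel axis is the standard reading for such
  self-attention gates.
* **Activation after fusion convolutions.** Every convolution is followed by
  BN + ReLU (the network's own convolution unit) unless the block equation
  supplies its own activation; `F_{122}` uses conv + ReLU exactly as its
  equation writes it, and the final RASF reduction convolution is linear so
  the residual identity holds exactly at zero weights.
* **Combining RASF's two paths.** `F_1'` and `F_2'` are concatenated before
  the reduction convolution (a summation alternative is available via the
  block constructor).
* **The normalisation written δ.** The AFF legend defines it as the L2 norm
  (applied here across channels per pixel, with ε = 1e-8 in the
  denominator); the network's general convention defines it as ReLU, which
  MPF's gate uses. Both are configurable per block.
* **AFF inputs at different widths.** The pooled tensor entering encoder
  level *k* carries the previous level's channel count, so the 3×3
  convolution inside AFF projects `low1` to `low2`'s width before global
  pooling; the channel-equality contract is enforced between that
  projection and `low2`.
* **Attention bottleneck.** The squeeze ratio r = 16 (conventional
  squeeze–excitation default, configurable); the hidden width is
  `max(1, C/r)`.
* **Channel plan.** Base width 32 doubled per level (32/64/128/256, bottleneck
  512), patch size 96, depth 4. Only the depth and the total parameter count
  of the original design are public; the width that reproduces its 9.3 M
  parameters is not recoverable, so the width is a configuration knob and the
  resulting count is reported, not forced.

## The compute engine

No tensor/autograd library is assumed: the package carries a small
reverse-mode automatic-differentiation engine over dense R arrays
(`H × W × batch × channel` internally), with convolutions implemented as
im2col block copies in compiled code feeding BLAS matrix products. Batch
normalisation keeps running statistics (momentum 0.1, ε = 1e-5) for
eval-mode inference; the 1×1 head bias initialises to −2 — the logit of the
~12% vessel prior — so early optimisation does not spend its few desk-scale
steps learning the class base rate; max-pooling records argmax positions for
its adjoint;
bilinear upsampling is a pair of sparse interpolation matrices applied along
each axis. Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8, with classic L2-style
weight decay added to the raw gradient. Predictions are clamped to
[1e-7, 1 − 1e-7] inside the loss, whose gradient is zeroed where the clamp
is active.

## The synthetic generator

Real fundus datasets cannot be redistributed with a package, so every stage
is testable against a procedural generator. It emulates: a dark circular
FOV (radius 0.48 of the image side) on a black background; a branching tree
of curvilinear vessels per root grown as a seeded random walk (step 1.5 px,
heading perturbation sd 0.12 rad, calibre taper 0.995 per step, side
branches with probability 0.03 per step inheriting 0.6–0.9 of the parent
calibre, growth stopping below 1 px); signed vessel/background contrast
(default −0.35: dark vessels as in real fundus images); low-frequency
background texture and additive Gaussian noise (sd 0.05; the texture
amplitude is tied to the noise level so a noise-free render is exactly
flat); Gaussian blur (σ = 0.8 px); and a pixel-exact binary label mask
rasterised *before* blur and noise by stamping disks of radius width/2 at
0.25 px intervals along each segment — a pixel is vessel iff its centre
falls inside any disk.

Root widths are drawn from 1.5–4 px and the branch probability was fixed so
that the mean vessel density is ≈ 12 % of the FOV, the density of real
fundus vasculature; with three root trees per 128 px image the generated
densities span roughly 5–20 %. What the generator does **not** emulate:
pathology (exudates, haemorrhages), the optic disc, colour (images are
grayscale with an optional 3-channel replication switch), and the
low-contrast texture of real capillary beds. Passing tests on synthetic
data therefore demonstrate that the implementation is correct and that the
network can learn curvilinear dark structures — not that it reaches
published accuracy on DRIVE/CHASE/STARE, which requires the real images and
GPU-scale training on 190,000 patches of 96 × 96.

## Patch protocol and inference

Training samples fixed-size windows uniformly over images and positions
(patch centres unconstrained by the FOV by default; an FOV-restricted mode
exists). Each image is z-scored inside its FOV before patching — some
normalisation is needed for stable training and this choice is switchable
off. The 80/20 split reproduces the published arithmetic: 190,000 patches
split into 152,000 for training and 38,000 for validation. Whole-image
inference tiles the image with stride = patch/2 by default (overlapping
windows reduce seam artifacts; stride = patch gives exact non-overlapping
round-trips), clamps the last row/column of windows to the border, and
averages all predictions covering a pixel.

## Evaluation

Confusion counts, sensitivity TP/(TP+FN), specificity TN/(FP+TN) and
accuracy (TP+TN)/total are computed over FOV pixels only (a switch
evaluates all pixels, since the original evaluation protocol does not state
the FOV convention); probabilities ≥ threshold count as positive and the
default threshold is 0.5. The ROC curve sweeps the distinct score values;
the trapezoidal area equals the Mann–Whitney probability that a random
vessel pixel outscores a random background pixel, with ties counted ½ — an
identity the tests assert to 1e-10. Zero denominators yield explicit `NA`s,
never silent zeros. Metrics are micro-averaged over all pooled test pixels,
with a per-image breakdown also reported.

## Numerical and degenerate-input conventions

* Dilated convolutions pad by their dilation so all parallel branches share
  the input's spatial size.
* Patch sizes must be divisible by 2⁴; anything else is rejected at
  configuration time.
* An all-zero FOV gives zero confusion counts and `NA` metrics; single-class
  pixel sets make the ROC refuse rather than return an arbitrary area.
* Ties at the binarisation threshold count as positive.
* Per-sample sub-seeds are derived as `seed + 9973·i`, keeping every derived
  seed a valid 32-bit integer; the same (parameters, seed) pair reproduces
  every array bit for bit.

## Scaled-down study sizes

The learning-sanity study that the tests and the acceptance script run uses
the full variant at base width 8 and patch size 32, trained for 5 epochs
with Adam (learning rate 1e-4, weight decay 1e-4, batch 16 — the published
optimiser settings) on 1,000 patches from 20 generated images (15 train,
5 held out), evaluated by stitched whole-image AUC. These sizes were chosen
as the smallest study at which training reliably separates vessels from
background on the generator's images; the expected outcome is held-out
AUC ≥ 0.9 after 5 epochs.

One caveat established empirically: an **untrained** network is at chance
only in expectation. Its output is a random projection of smooth rectified
features, which can correlate (either way) with the dominant intensity
structure — across initialisation seeds the untrained AUC averages 0.50 but
single draws range roughly 0.2–0.8. The chance-level test therefore
averages over several initialisations; a single-seed comparison against an
untrained model can land in a tail.

## Known limitations

* CPU-only, single-threaded by design; wall-clock scales linearly with
  patch count and quadratically with patch side.
* No data augmentation (the original training protocol mentions none).
* The loader supports PNG/TIFF/PPM/PGM (and JPEG via EBImage); GIF
  annotations must be converted first.
* Leave-one-out utilities build the folds; orchestrating a full
  cross-validated training campaign is left to user scripts.
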