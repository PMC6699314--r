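---
title: "Methods: residual encoder-decoder segmentation of short-axis cardiac MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual encoder-decoder segmentation of short-axis cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative cardiac function analysis from short-axis cine MR requires
delineating three structures on every end-diastolic (ED) and end-systolic
(ES) frame: the left-ventricular (LV) blood pool, the LV myocardium and the
right-ventricular (RV) blood pool. Doing this manually across a stack of
slices and many subjects is slow and operator-dependent; free-breathing
real-time acquisitions make it harder still because of lower SNR and
respiratory motion. `heartseg` implements a one-stage deep-learning
segmenter for this task: a single convolutional network that both locates
the heart and labels every pixel, with no prior localization step.

Throughout the package, label maps use the convention
**1 = background, 2 = RV blood pool, 3 = LV myocardium, 4 = LV blood
pool**, and images are processed on a fixed 160 x 128 grid.

## The network

The segmenter (`net_spec()`, `build_network()`) is an encoder-decoder
(U-Net-style) network built from *residual blocks*. Each block has

* a main path: 3x3 convolution -> batch norm -> ReLU -> 3x3 convolution ->
  batch norm;
* a shortcut path: 1x1 convolution -> batch norm (applied even when the
  channel counts match, so the block always has a learnable projection);
* output: ReLU(main + shortcut).

The encoder applies one residual block and one 2x2 max pooling per level,
with channel widths `base_width * growth^(level-1)` — 24, 48, 96, 192 by
default over four levels, so a 160 x 128 input reaches the 10 x 8
bottleneck at width 384. The bottleneck block is followed by dropout (rate
0.5) as the only explicit stochastic regularizer inside the network. The
decoder mirrors the encoder: a 2x2 transposed convolution doubles the grid
and halves the channels, the matching encoder feature map is concatenated
(skip connection), and a residual block fuses the two. A 1x1 convolution
maps the final 24 channels to K = 4 classes and a per-pixel SoftMax yields
class probabilities. All convolutions are same-padded, so the output grid
always equals the input grid and skip concatenation needs no cropping.

Two points in the block description were genuinely open and were fixed as
follows: BN is inserted after every convolution with ReLU following
(conv -> BN -> ReLU ordering), and the decoder reuses the same residual
block type as the encoder. With those choices the default network counts
4,565,788 trainable scalars (4.57 million; convolutions adjacent to BN
carry no bias, transposed convolutions and the head do). A conventional
U-Net with plain double-convolution blocks and 64 initial filters
(`build_unet_baseline()`) counts 31.0 million under the same counting
rules and serves as the comparison arm.

The layers, back-propagation and the ADAM optimizer are implemented in the
package itself (R with compiled im2col/pooling/pixel-shuffle kernels;
matrix products go through BLAS). Backward passes are verified against
central finite differences in the test suite, end to end through BN,
pooling and the losses.

## The loss

Class imbalance is severe in this task: background dominates, and the
myocardial annulus is thin. The package implements the generalized Dice
loss

$$\mathrm{Loss} = 1 - 2\,
\frac{\sum_k w_k \sum_m Y_{km} T_{km}}
     {\sum_k w_k \sum_m (Y_{km}^2 + T_{km}^2)},
\qquad w_k = \frac{1}{(\sum_m T_{km})^2},$$

where $Y$ is the predicted probability stack, $T$ the one-hot ground truth,
$K$ the number of classes and $M$ the number of pixels. The inverse-square
size weight equalizes the influence of large and small structures — but it
is *infinite* when class $k$ has no pixels in $T$, which genuinely happens
on apex slices (no RV) and on partially labeled data. `gdl_weights()` and
`generalized_dice_loss()` implement this baseline faithfully, including the
failure (an absent class raises an error rather than silently producing
NaN).

The improved variant (`improved_generalized_dice_loss()`) removes the
defect:

$$\mathrm{Loss} = 1 - 2\,
\frac{\sum_k w_k \sum_m Y_{km} T_{km} + \varepsilon}
     {\sum_k w_k \sum_m (Y_{km}^2 + T_{km}^2) + \varepsilon},
\qquad w_k = \begin{cases}
1/\sum_m T_{km} & \text{class present} \\
1/(\sum_m Y_{km} + \varepsilon) & \text{class absent,}
\end{cases}$$

with $\varepsilon = 10^{-8}$. When a class is absent its weight is taken
from the predicted mass instead: predicting nothing for an absent class is
costless, predicting much is penalized with a weight that shrinks as the
false mass grows, and every quantity stays finite. The exact form of the
absent-class weight is not uniquely determined by its verbal description;
$w_k = 1/(\sum_m Y_{km} + \varepsilon)$ is the direct analogue of the
present-class rule and is isolated in `igd_weights()` so it can be swapped.
$\varepsilon$ enters the numerator and denominator once (not per class).
The analytic gradient (`improved_gdl_grad()`) includes the dependence of
the absent-class weights on $Y$ and is finite everywhere on the probability
simplex; the test suite checks it by finite differences on instances with
and without absent classes. Pixel-wise cross-entropy is provided as the
comparison arm. Losses are computed per minibatch item and averaged, so the
loss scale does not depend on the batch size.

## Preprocessing

`preprocess_pipeline()` follows the chain: bilinear resize to 160 x 128
(half-pixel-centered coordinates, no cropping or padding — the full field
of view is always retained), per-image min-max normalization of 16-bit
input to 8-bit (a constant image maps to zero), contrast-limited adaptive
histogram equalization, and division by 255 to unit floats. CLAHE is
delegated to `EBImage::clahe()` (Zuiderveld's tile-based algorithm with
bilinear blending between tile mappings); the configured clip fraction
`f` (default 0.01) maps to a clip limit of `f * 256` times the average
histogram bin height, with an 8 x 8 tile grid by default. Labels are
resized with nearest-neighbor interpolation only — fractional class values
are meaningless — so the output value set is always a subset of the input's.

## On-the-fly augmentation

During training each minibatch item receives a freshly sampled transform
(`sample_transform()`): an affine map (scaling, rotation, shearing about
the image center, then translation), additive Gaussian noise, Gaussian
blur and elastic deformation, each included independently with probability
0.5 and parameters drawn uniformly from configured ranges (defaults:
scale 0.9–1.1, rotation ±15°, shear ±8°, translation ±10 px, noise sigma
0–0.03 on the unit scale, blur sigma 0–1.5 px, elastic amplitude 0–10 px
with smoothness 4–8 px). The elastic field is smoothed unit-variance
Gaussian noise scaled by the amplitude. Images are resampled bilinearly
(out-of-bounds fill 0), labels with nearest-neighbor through the same
geometry (fill 1 = background); noise and blur touch the image only.
Augmented items exist only in memory for the lifetime of their minibatch —
nothing is written to disk, and the test suite watches the filesystem to
prove it. A sampled transform is a plain serializable list, so any
augmented item can be reproduced exactly.

The magnitudes above are not prescribed by the training schedule we follow
(which names only the transform families); they are conservative choices
for 160 x 128 cardiac frames, and whether one transform is shared across a
minibatch was also open — per-item sampling is implemented.

## Training schedule

`train()` implements: ADAM (moments 0.9/0.999), initial learning rate
1e-3 decayed by 0.98 per epoch and restored to 1e-3 every 100 epochs
(`lr_schedule()`), L2 weight decay 1e-4 added to the loss (applied to
convolution kernels; gradient contribution `2 * l2 * W`), minibatch 16
with drop-last batching, per-epoch seeded shuffling, He weight
initialization, and best-model selection on validation mean Dice with an
early-stop patience of 50 epochs (the patience value is not prescribed
anywhere and is a configurable default). Validation images are
preprocessed but never augmented. After training, the batch-norm running
statistics of the returned model are *finalized*: exact population moments
are recomputed in one pass over the unaugmented training images
(`finalize_bn_stats()`), as the deep-learning toolbox used to train the
original model does after its last iteration. This matters for short
schedules, where the exponentially-weighted moving statistics lag the
weights; the per-epoch history still uses the cheap moving statistics. With drop-last batching a training set
of 1902 images yields `floor(1902/16) * 16 * 200 = 377,600` augmented
images over 200 epochs (`images_seen()`). Runs are bit-reproducible for a
fixed seed on one device: all randomness (initialization, shuffling,
augmentation, dropout) flows through one seeded stream, and R's global
random state is never touched.

## The phantom generator

`generate_phantom()` synthesizes short-axis frames so the full pipeline is
testable and demonstrable without any data download: a circular LV blood
pool inside a concentric myocardial annulus, an RV crescent attached to
the left of the annulus (an offset disk minus the LV+wall disk — the
simplest shape with the right topology), SSFP-like intensity ordering
blood > myocardium > background (defaults 42000 / 20000 / 7000 on the
16-bit scale), a smooth additive quadratic bias field (amplitude 5000) and
additive Gaussian noise (sigma 1800; Rician noise is not emulated — at this
SNR the distinction is immaterial for exercising the pipeline). ES frames
contract the LV cavity radius to 0.8 of its ED value while keeping the
outer wall boundary, so the wall thickens as in systole and the ES LV area
is strictly smaller. Slice modes emulate position along the long axis:
`apex` shrinks the ventricle by 0.55 and omits the RV entirely — producing
genuinely absent classes that exercise the improved-loss path — and `base`
adds a bright unlabeled distractor blob outside the heart, standing in for
out-of-plane vessels. `generate_dataset()` mixes phases, modes (25% apex /
50% mid / 25% base in expectation, with at least one apex frame forced
into any mixed set of four or more) and respiratory shifts of ±6 px.

What the phantoms deliberately do not emulate: k-space acquisition and
SSFP banding, anatomical shape variability, papillary muscles, trabeculae,
partial-volume fuzz at boundaries, and inter-subject intensity
distribution shifts. Passing phantom tests therefore demonstrates that the
optimization, loss and evaluation machinery work — that the network can
learn geometry + contrast rules under noise, bias fields and augmentation —
not that clinical-grade accuracy would be reached on real cine MR, which
requires training on real annotated data at GPU scale.

## Numerical choices

* Resize dialect: half-pixel-centered source coordinates, border values
  extended (no cropping); fixed and tested because resize dialects differ
  silently between libraries.
* 8-bit normalization of a constant image returns all zeros (the min-max
  rule's degenerate case, declared rather than NaN).
* Argmax ties in `predict()` break toward the lower label value, i.e.
  toward background — a deterministic, conservative rule.
* Metric empty-set rules: a class absent from both maps is excluded from
  means (an apex slice should neither reward nor punish an RV score); a
  class absent from exactly one map scores 0. Per-image metrics are
  averaged per class, then classes averaged, mirroring per-structure
  reporting tables.
* BN uses biased batch variance, running-statistic momentum 0.9 and
  eps 1e-5; evaluation-mode forwards use running statistics and are
  deterministic.
* The generalized-Dice weight is implemented as `1/(sum T)^2` (the
  squared-sum reading of the ambiguous typeset formula, following the
  cited formulation); the improved weight is `1/sum T` as printed.
* Training aborts with a diagnostic if the loss becomes non-finite.

## Desk-scale problem sizes

The package's own end-to-end experiments (test suite and worked examples)
run on one CPU at reduced scale: a base-width-8, 3-level network trained
for 15 epochs on 128 mid-ventricular phantom frames at 160 x 128 with 32
held-out frames for validation; and a 3-seed loss-ablation comparison
(improved generalized Dice + augmentation vs cross-entropy) on
apex-containing sets at 64 x 64, 48 training frames, 30 epochs. These
sizes are the package's choice of a demonstration scale: large enough
that the arms are past their initial plateau and the comparison carries
signal, small enough to run routinely.

A dynamic worth knowing about when reading short-schedule results:
Dice-family losses back-propagate through the SoftMax as
$P \odot (g - \langle g, P\rangle)$, so a class the network has driven to
near-zero probability everywhere receives almost no gradient and revives
only slowly ("dead class"). The RV — distinguishable from the LV blood
pool only by position, not intensity — regularly spends the first
~100 optimizer steps dead and is always the last structure to appear;
long schedules (the published one runs 23,600 steps) make this invisible,
desk-scale ones do not. Cross-entropy, whose logit gradient $P - T$ does
not vanish on dead classes, revives them sooner in exchange for its
class-imbalance handicap. The directional expectation — the improved loss
with augmentation matching or beating cross-entropy on sets containing
apex (absent-RV) slices — mirrors the ordering reported on real data
without claiming its numbers.

## Known limitations

* Strictly 2-D: volumes are segmented slice by slice; no through-plane
  context, no cine temporal context.
* The published per-structure accuracy on real ACDC / free-breathing data
  is out of desk-scale reach by design (it requires the real datasets and
  GPU-scale training); the package reproduces the architecture, loss,
  schedule and evaluation machinery, and its parameter-count and
  throughput figures, not the clinical Dice table.
* Single-device determinism only; bit-equality across BLAS
  implementations is not promised.
* Basal slices with distractor structures remain the hardest mode for the
  phantom experiments too — consistent with the failure mode reported on
  real data.
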