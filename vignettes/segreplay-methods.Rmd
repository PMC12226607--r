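---
title: "Diffusion-driven generative replay for class-incremental segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-driven generative replay for class-incremental segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(segreplay)
```

## The problem

Class-incremental semantic segmentation (CISS) extends a segmentation model
to new classes over a sequence of training steps without revisiting the old
training images. In clinical imaging the constraint is structural, not
merely practical: incremental data arrives as *new patient images* with
annotations for the *new* structures only, and old images cannot be retained
or re-annotated. Surgical anatomy datasets sharpen the problem further with
a **binary-annotation regime**: each image carries a pixel mask for exactly
one designated ("most prominent") structure, while every other visible
structure — including ones the model already knows — stays unlabeled.

Trained naively, the model collapses on previously learned classes
(**catastrophic forgetting**): the new step's loss treats every non-annotated
pixel as background, so old-class evidence is actively suppressed.

`segreplay` implements a three-component remedy:

1. **Generative replay.** An unconditional denoising diffusion probabilistic
   model (DDPM) is trained once on the initial step's images and frozen.
   At each incremental step it synthesizes a replay set of images that stand
   in for the inaccessible old data.
2. **Dense feature distillation.** The previous step's frozen model
   `M^(t-1)` and the trainable `M^t` process the same inputs; a weighted
   Euclidean penalty across a declared layer set (encoder features, context
   block, logits) keeps the new model's representations close to its
   predecessor's.
3. **Cross-model contrastive learning.** An InfoNCE-style loss pulls
   together the two models' pooled encoder features of the same real image
   (the positive pair) and pushes apart a real image's current-model feature
   from a generated image's features under either model (the two negatives).

Supervision combines ground truth with **pseudo-labels**: outside the
annotated mask, pixels take the frozen previous model's prediction wherever
its softmax confidence reaches a threshold, and the ignore id (255)
otherwise — on generated images, which have no ground truth, the label map
is pure thresholded pseudo-labels.

## The model, precisely

### Diffusion generator

The forward process perturbs a clean image $x_0$ at step
$s \in \{1, \dots, S\}$:

$$x_s = \sqrt{\bar\alpha_s}\, x_0 + \sqrt{1 - \bar\alpha_s}\, \epsilon,
\qquad \epsilon \sim \mathcal N(0, I),$$

with $\alpha_s = 1 - \beta_s$ and $\bar\alpha_s = \prod_{u \le s} \alpha_u$.
The noise predictor $\epsilon_\theta(x_s, s)$ is trained to minimize the
mean squared discrepancy $\lVert \epsilon - \epsilon_\theta(x_s, s)
\rVert^2$ (reduced as the mean over elements, so the objective is invariant
to image size). Sampling starts from $x_S \sim \mathcal N(0, I)$ and applies
the ancestral update

$$x_{s-1} = \frac{1}{\sqrt{\alpha_s}}\left(x_s -
\frac{1-\alpha_s}{\sqrt{1-\bar\alpha_s}}\,\epsilon_\theta(x_s, s)\right)
+ \sigma_s z,$$

with $z \sim \mathcal N(0, I)$ for $s > 1$ and $z = 0$ at $s = 1$.

Numerical conventions, chosen once:

* **Schedule.** $\beta$ linear from $10^{-4}$ to $0.02$ (the original DDPM
  convention); $\sigma_s^2 = \beta_s$ with $\sigma_1$ forced to 0,
  consistent with the deterministic final step.
* **Value range.** Images live in $[-1, 1]$; 8-bit PNGs map as
  $v/127.5 - 1$. Sampled images are clipped to $[-1, 1]$ on export;
  intermediate grids are unbounded.
* **Correctness oracle.** For standard-normal data the posterior-expected
  noise has the closed form $\epsilon^*(x, s) = \sqrt{1-\bar\alpha_s}\,x$;
  under this oracle every reverse step reduces to
  $x \mapsto \sqrt{\alpha_s}\,x + \sigma_s z$, whose stationary variance
  is 1. The test suite draws 2,000 ancestral samples under the oracle and
  checks the first two moments — an end-to-end check of the sampling loop
  with no trained network involved.

### Backbones

No deep-learning framework is assumed: the package carries its own small
convolution engine (im2col lowering to BLAS matrix multiplies, explicit
analytic gradients, checked against finite differences in the test suite).
The segmentation backbone is a compact fully-convolutional encoder–decoder:
a 3×3 encoder convolution, a dilated 3×3 context convolution standing in for
atrous spatial pyramid pooling at desk scale, and a 1×1 classification head.
It exposes the `seg_outputs` contract — logits, the ordered embedding list
used for distillation (`encoder`, `context`, `logits`), and a globally
pooled encoder feature `z` — so larger backbones can be slotted in behind
the same interface. The noise predictor is the same engine plus a sinusoidal
step embedding injected as a per-channel bias after the first convolution.

The classification head grows by appending channels for new classes,
initialized with small random weights; pre-existing channel parameters are
bit-identical afterwards, so old-class logits are unchanged on any input
(verified bitwise in the tests).

### Losses

* **Weighted cross-entropy** over non-ignored pixels, with inverse pixel
  frequency class weights (one pixel of additive smoothing), normalized to
  mean 1 over the classes present; a registry class absent from the data
  receives the maximum computed weight.
* **Distillation** `kd_loss()` is the weighted sum over the layer set of
  plain Euclidean distances between flattened embeddings (a squared variant
  is a config switch). After head expansion the logits layer is compared on
  the previous model's channels only.
* **Contrast** uses a two-affine-layer projection head with L2-normalized
  outputs, so similarities are cosines; the temperature divides the
  similarities inside the softmax. Each real image in a batch is paired
  with one generated image drawn uniformly from the replay portion of the
  same batch, giving exactly two negatives (the generated image under the
  current and the previous model). Other real images are *not* used as
  negatives. The batch value is the mean over real images.
* **Overall.** At the initial step only the segmentation term applies;
  incremental steps sum the three terms with multipliers defaulting to 1.

### A scale correction the trainer applies to distillation

The raw Euclidean distance has a gradient of norm exactly $\omega_l$ per
layer per image, *independent of how far the features have drifted*, while
the pixel-averaged cross-entropy gradient at these problem sizes has norm
around $0.03$. With unit layer weights the distillation pull is therefore
~30× the supervision signal; in our experiments the model then fits neither
old nor new classes (all-class Dice collapses toward 0). The trainer
consequently normalizes each layer's distance by the square root of its
element count — an RMS distance — making the configured $\omega_l$
(default 1) scale-free multipliers that are comparable across layers and to
the cross-entropy term. `kd_loss()` itself keeps the raw weighted-Euclidean
contract; the normalization is a trainer policy, visible and overridable
through `omega`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `diffusion$S` | 50 | diffusion steps (desk scale; unitless count) |
| `diffusion$beta_start/end` | 1e-4 / 0.02 | linear variance schedule endpoints |
| `diffusion$epochs`, `lr` | 20, 1e-3 | AdamW training of the noise predictor |
| `replay$N` | 60 | generated images per replay set |
| `replay$ratio` | 0.5 | replay fraction of each incremental batch |
| `seg$width` | 16 | hidden channels of both backbones |
| `seg$epochs`, `lr`, `momentum` | 10, 1e-2, 0.9 | SGD per incremental step; at 10 desk-scale epochs the rate is held constant (a decaying schedule starves the shorter no-replay arms of late progress on new classes) |
| `losses$omega` | 1, 1, 1 | distillation layer multipliers (RMS-normalized by the trainer) |
| `losses$tau` | 0.1 | contrastive temperature |
| `losses$threshold` | 0.7 | pseudo-label confidence threshold |
| `losses$multipliers` | 1, 1, 1 | seg / kd / cl weights in the overall loss |

Every knob lives in one nested config (`default_config()`), can be set from
YAML (`load_run_config()`), and is logged with the run.

## The synthetic benchmark

`scene_spec()` emulates the binary-annotation regime at desk scale: 5
classes, 32×32 images, 60 images per class, each scene a textured
low-frequency background with 1–2 randomized superellipse blobs of the
designated class (smooth shading plus Gaussian texture) and 0–2 unannotated
*distractor* blobs of other classes — mirroring datasets where co-visible
structures stay unlabeled. The mask covers exactly the designated-class
blobs; foreground fraction is kept within [0.02, 0.5]. Splits are 70/10/20
per class, and the class-incremental partitions (3–2 by default, 3–1–1
available) put new classes on disjoint images.

What the generator deliberately does **not** model: photorealistic organ
appearance, laparoscope optics, specular highlights, smoke, occlusion
boundaries, or class-dependent spatial layout. Classes are separable mainly
by color and texture, so a small network can learn them in minutes. Passing
the benchmark therefore demonstrates that the *mechanics* of the framework
(replay, distillation, contrast, pseudo-labeling, head growth, freezing)
behave correctly and that forgetting dynamics order as expected — it does
not certify segmentation quality on real surgical imagery.

One consequence of the distractor policy is worth stating: because old-class
structures remain visible (unannotated) in new-step images, confident
pseudo-labels alone already recover much of the old-class performance in
this synthetic world; the measured gaps between the distillation/replay/
contrast arms are correspondingly smaller than in GPU-scale experiments on
real data, though their ordering is preserved.

## The forgetting benchmark

`forgetting_benchmark()` builds the default dataset, trains the initial
step once per seed (the initial step is method-independent), then runs the
incremental step under four arms:

* `fine-tune` — ground-truth-only cross-entropy on the new data;
* `kd` — adds pseudo-labels and feature distillation;
* `kd+dg` — adds the diffusion replay set;
* `kd+dg+cl` — the full method, adding the contrastive term.

Old-class and new-class mean Dice are scored on held-out test images, with
medians over 3 derived seeds. The acceptance checks assert the fine-tuning
collapse (old-class Dice below 0.05), a ≥ 0.30 old-class advantage of the
full method, and the component ordering
`fine-tune < kd ≤ kd+dg ≤ kd+dg+cl`.

Problem sizes used throughout the checks — 32×32 images, width-16 networks,
10 segmentation epochs, 20 diffusion epochs, 60 replay images, 3 seeds —
are the package's desk-scale defaults, chosen so the full protocol runs in
minutes on one CPU core.

## Numerical and policy choices on genuinely open points

* **Dice reduction.** Per class, Dice is computed *only* on test images
  whose annotated class is that class, comparing the model's class mask to
  the binary ground truth, then averaged over those images
  (image-averaged, not pixel-pooled). This matches the one-class-per-image
  structure of the annotation regime; predictions of other classes on an
  image are not counted against it, because no ground truth exists for
  them there.
* **Group deviations** in reports are population (N-divisor) standard
  deviations across the per-class values of a group, switchable to the
  sample convention. Display rounding is 2 decimals; JSON keeps full
  precision.
* **Ties** in per-pixel argmax break toward the lowest channel index
  (background first) — deterministic and documented.
* **Pseudo-label fallback.** Below-threshold pixels get the ignore id
  rather than background, so uncertain regions contribute nothing to the
  loss instead of actively erasing old classes.
* **Distance form.** The distillation distance is the plain Euclidean norm
  as stated by its definition, with a squared-distance config switch.
* **Pseudo-labels are cached** once per step (a config flag allows
  re-deriving them each epoch; the frozen model does not change within a
  step, so caching is exact, not an approximation).
* **Degenerate inputs.** Empty masks score Dice 1 against empty
  predictions and 0 otherwise; an all-ignored label map yields loss 0 with
  a warning; a zero-norm projection falls back to a fixed basis vector.
* **Determinism.** Every random draw flows from one master seed through
  tagged sub-seeds (`derive_seed()`), so runs are bit-reproducible; the
  trainer's RNG state never leaks into the caller's session.

## Known limitations

* The backbones are deliberately tiny; nothing in the contracts prevents
  plugging in a larger encoder–decoder, but the package does not ship one.
* Replay quality is not assessed by generative metrics (inception-style
  scores are out of scope); the replay set's value is measured only through
  its effect on forgetting.
* The contrastive term operates at image level on pooled features;
  pixel- or region-level variants, memory banks and momentum encoders are
  out of scope.
* Boundary refinement, CRF post-processing and test-time augmentation are
  out of scope.
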