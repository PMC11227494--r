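---
title: "Label-efficient echocardiogram classification with echoclr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-efficient echocardiogram classification with echoclr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transthoracic echocardiography produces multi-view grayscale ultrasound
videos, and supervised deep learning on such videos needs thousands of
expert-labeled studies. `echoclr` implements a self-supervised pretraining
strategy for parasternal-long-axis (PLAX) echocardiogram videos that makes
downstream disease classifiers — here left ventricular hypertrophy (LVH) and
severe aortic stenosis (AS) — far more label-efficient: the encoder first
learns from unlabeled videos, then is fine-tuned on a small labeled subset.

Two ideas are combined, both motivated by properties of ultrasound:

1. **Multi-instance contrastive learning.** Standard contrastive learning
   (SimCLR-style) manufactures two "views" of an image with heavy
   augmentation, which would destroy the low-contrast diagnostic signal of
   ultrasound. Instead, a routine echo study contains several genuinely
   distinct PLAX videos of the same heart; any two videos of one study form
   a *positive pair*, and videos of different studies are negatives.
2. **Frame reordering.** Echo videos carry rich temporal structure (the
   cardiac cycle). The frames of each sampled K-frame clip are randomly
   permuted and the model must classify which of the K! orderings was
   applied, forcing temporally coherent representations.

## Model and objectives

The encoder `f` is an 18-layer 3D residual network (`encoder_r3d18()`):
a 3×7×7 stem convolution with spatial stride 2, four stages of two basic
residual blocks (64/128/256/512 channels; stages 2–4 stride 2 in every
dimension), global average pooling, and a 512-dimensional representation
*h*. Grayscale clips are replicated to three channels to match the stem.
A projector `g` (`projector_mlp()`, 512 → 256 → ReLU → 128) produces the
embedding *z* used by the contrastive loss; the reorder head is one fully
connected layer from *h* to K! logits.

For a batch of N positive pairs (2N clips), with cosine similarity
`sim(u, v)` and temperature τ:

$$\ell_{i,j} = -\log \frac{\exp(\mathrm{sim}(z_i, z_j)/\tau)}
{\sum_{k=1}^{2N} \mathbb{1}[i \neq k]\, \exp(\mathrm{sim}(z_i, z_k)/\tau)}$$

and `nt_xent_loss()` returns the mean of $\ell$ over both orderings of every
pair. The reorder loss is the K!-way cross-entropy between the predicted
logits and the lexicographic rank (Lehmer code, `permutation_rank()`) of the
applied permutation; its chance level is exactly $\ln K!$. The EchoCLR
training loss is the *unweighted sum* of the two. Three pretraining modes
are supported (`pretrain_config()`): `EchoCLR` (pairs + reordering),
`MI-SimCLR` (pairs only), and `SimCLR` (two independent augmentations of a
single clip, no reordering); one epoch visits every positive pair (pair
modes) or every video (SimCLR), and `match_epoch_budget()` equalizes the
number of examples seen across the two schemes.

Key defaults follow the reference protocol: clip length K = 4 for
pretraining (enough temporal information while keeping K! = 24 classes
tractable and avoiding repeated cardiac phases), τ = 0.5, Adam at learning
rate 0.1, batch size 392, 300 pair-epochs; fine-tuning uses 16-frame clips,
binary cross-entropy, a maximum of 30 epochs with patience-5 early stopping
(the checkpoint returned is the validation-loss argmin), and the
titration-dependent learning-rate grids exposed by `lr_grid()` with
`select_learning_rate()` picking the grid entry with minimal validation
loss at the early-stopping checkpoint (ties to the larger rate).

### Design choices where the protocol is open

* **Shuffled clips feed both objectives.** The contrastive branch sees the
  same frame-shuffled clips as the reorder head (shuffle-then-encode), which
  matches the single-forward-pass design; both members of a pair contribute
  reorder terms.
* **Reorder head input.** The reorder head consumes the pooled
  representation *h*, not the projection *z*: the representation, not the
  contrastive embedding, is what transfers downstream.
* **Augmentation is clip-consistent.** One parameter draw (pad, flip,
  rotation) per clip, applied identically to every frame. Per-frame
  independent geometry would corrupt exactly the temporal signal the
  reordering task is meant to exploit.
* **Zero padding = pad-then-crop.** "Random zero padding by up to 8 pixels
  per spatial dimension" is implemented as symmetric zero padding by
  p ∈ {0..8} pixels per side followed by a random crop back to the input
  size, keeping tensor shapes fixed. The 8-pixel default is calibrated to
  112×112 inputs; desk-scale runs on smaller frames scale it down
  (e.g. 2 px at 32×32) so the translation fraction is comparable.
* **Titration and splits use floor rounding**, the only rule consistent
  with all twelve published study counts (e.g. 5194 × 0.01 = 51.94 → 51;
  5311 × 0.25 = 1327.75 → 1327), and titration is simple random without
  label stratification.
* **Hull per video, not per frame.** Content masking computes one convex
  hull from the union of thresholded frames; a per-frame hull would jitter
  the field of view over time. Binarization uses ≥ threshold (includes
  saturated pixels); view retention is plain argmax == "PLAX" with no extra
  confidence floor.
* **Short videos are loop-padded** (frame t ↦ t mod T) rather than
  zero-padded, preserving periodic motion.
* **Kinetics-400 initialization** is supported only through an externally
  supplied weights file plus channel statistics; nothing is downloaded, and
  when used, clips are channel-standardized with the supplied mean/sd.

## The synthetic cohort generator

Clinical echocardiograms cannot be redistributed, so `generate_cohort()`
produces cohorts with the statistical structure the method actually relies
on:

* a **sector-fan geometry** — bright fan on an exactly-zero background with
  a bright sector outline, so threshold-and-hull masking behaves as it does
  on clinical scans;
* **multiplicative speckle** (gamma-distributed, mean 1);
* a **ventricular wall ring** whose radius oscillates sinusoidally with a
  configurable period; the fractional excursion is 0.25, in the range of
  normal LV fractional shortening, and each video starts at a random
  cardiac phase as real acquisitions do;
* **per-study anatomy** (`study_anatomy()`): cavity radius and wall
  thickness multipliers in \[0.85, 1.15\] and small center offsets, drawn
  deterministically per study id. All videos of a study share one heart
  while hearts vary continuously across studies — this is what makes
  same-study retrieval a meaningful (and non-trivial) contrastive task;
* a **planted geometric disease signal**: diseased studies have a wall
  thicker by `effect_size` × the healthy base thickness. The signal is
  structural rather than textural, mirroring how LVH is defined, so masking
  and downsampling cannot erase it;
* **labels** follow the clinical rules: LVH iff LVMI strictly exceeds
  95 g/m² (women) / 115 g/m² (men), with LVMI sampled on the correct side
  of the threshold; AS severity binarized as severe vs everything else. A
  configurable fraction of studies has missing LVMI (label NA — usable for
  pretraining, skipped in fine-tuning), mirroring cohorts where LVH labels
  exist only for a subset.

Defaults describe the standard conditions: 112×112 frames, 32 frames/video
at 30 fps, 2–3 videos per study, prevalence 0.25, effect size 0.75, full
speckle, 16-frame motion period. Videos are written as uncompressed 8-bit
grayscale AVI — bit-exact on round-trip, which the tests rely on.

What the generator does **not** emulate: beamforming physics, Doppler,
off-axis probe motion, interleaved anatomy (valves, atria), or
device/operator variability. Passing tests on fixtures therefore
demonstrates that the pipeline's machinery is correct and that the method
can exploit study-level structure and temporal order — not clinical-grade
performance.

## Desk-scale evaluation protocol

The full 3D-ResNet18 at the native resolution is GPU-scale; the package
therefore treats a reduced encoder (`encoder_tiny()`: three stride-2 3D
convolutions, batch norm, 512-d output via a final linear layer) as a
first-class configuration for CPU-scale experiments, with the full
architecture remaining the default. The learnability experiments in the
test suite and acceptance script use:

* a 300-study cohort, 32×32 frames, 12 frames/video, motion period 8,
  2–3 videos per study, prevalence 0.25;
* **effect size 0.3** for the fine-tuning comparison. With ±15% anatomical
  variation, a 30% thickening overlaps the healthy distribution; at large
  effect sizes the task saturates (test AUROC 1.0 from a handful of labels
  under any initialization), and a saturated task cannot discriminate
  initialization quality. The choice is driven by that separability
  argument, not by the method;
* EchoCLR pretraining for 20 epochs (tiny encoder, lr 0.005, batch 32,
  pad 2), then fine-tuning at the 5% titration (11 of 225 training
  studies) over 5 seeds and a 2-point learning-rate grid {1e-2, 1e-3} per
  run, selected by validation loss — the same grid-selection protocol as
  the reference procedure, which is what makes small-label runs stable
  enough to compare;
* 8-frame fine-tuning clips (the videos are 12 frames long; 16-frame clips
  would be half loop-padding).

Numerical notes: NT-Xent is computed with a numerically safe softmax
(max-shifted log-sum-exp in the reorder loss; cosine similarities bounded);
zero-norm embeddings raise an error rather than NaN; bootstrap resamples
with a single class are skipped and counted; `bootstrap_auroc_pvalue()`
returns p = 0.5 at zero difference with zero variance. AUROC uses midranks
(ties count ½), AUPR is step-wise average precision without interpolation,
and bootstrap CIs are percentile CIs over study-level resamples
(B = 10,000 by default; the difference test uses B = 2,000).

## Saliency

`gradcam_volume()` implements Grad-CAM at the last convolution block of the
3D encoder: channel weights are the gradients of the positive-class
pre-sigmoid logit, global-average-pooled over all three grid axes (the
canonical generalization to 3D); the weighted activation sum is
ReLU-rectified. For the default encoder on a 112×112×32 clip the grid is
7×7×4 (height × width × time). `project_saliency()` upsamples with
separable natural cubic splines to 112×112×32 and takes the pixelwise
temporal maximum to produce one 2D heatmap.

## Known limitations

* The reduced encoder trades capacity for CPU tractability; absolute
  AUROC values on fixtures are not comparable to clinical results.
* The view-classification harness is a contract (any frame → named
  probability vector function); no pretrained clinical view classifier is
  shipped.
* The generator's disease model is purely geometric; textural or
  hemodynamic signals (e.g. Doppler-derived) are out of scope.
* Training is single-threaded CPU; no multi-GPU data parallelism.
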