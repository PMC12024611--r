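---
title: "Feedback pseudo-label learning for ordinal acne grading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback pseudo-label learning for ordinal acne grading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `acnegrader`, the
assumptions behind them, the tunable parameters and their defaults, and the
numerical and design choices that were genuinely open. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## The problem

Clinical acne severity is graded per face image on a four-level ordinal
scale (0–3, mild to very severe). Expert-labeled images are scarce —
privacy constraints and annotation cost keep labeled sets in the hundreds —
while unlabeled face images are plentiful. The package implements a
semi-supervised training framework for this regime, together with the
toolchain around it: facial-skin segmentation to remove background clutter,
a lesion-safe augmentation policy, clinical evaluation metrics, and image
de-identification.

## Feedback pseudo-label learning

A *teacher* network and a *student* network are trained in alternation.
At each step:

1. The teacher predicts class probabilities on an unlabeled batch. Samples
   whose maximum probability reaches the confidence threshold (default
   0.95) become hard pseudo-labels; the rest are rejected. The default is
   the argmax label; categorical sampling is available (`pseudo_mode`).
2. The student takes one optimizer step on the accepted pseudo-labeled
   samples *only* — it never sees labeled data directly.
3. The student's labeled-loss gradient after its update and its
   pseudo-label-loss gradient before it are condensed into one scalar,
   \(h = \eta_s \,\langle g_l(\theta_S^{t+1}),\, g_u(\theta_S^{t})\rangle\),
   the *feedback coefficient*: positive when the pseudo-label step moved
   the student in a direction that also helps on labeled data.
4. The teacher is updated on the sum of three gradients: \(h\) times its
   own gradient on the pseudo-labeled batch (feedback), a plain supervised
   gradient on the labeled batch, and an augmentation-consistency (UDA)
   gradient — the cross-entropy between its temperature-sharpened,
   gradient-blocked prediction on clean images and its prediction on
   augmented views.

The trained **student** is the returned model. On a small model where the
expectation over the pseudo-label draw can be enumerated, the feedback
gradient agrees to first order in \(\eta_s\) with direct differentiation of
the unrolled objective
\(L_l(\theta_S - \eta_s \nabla_{\theta_S} L_u(\theta_T, \theta_S))\) with
respect to the teacher parameters; the test suite verifies this against
central finite differences. The identity is per-sample: with a batch of
\(B\) pseudo-labeled samples the batch-mean appears in both factors, so the
estimator is scaled by \(1/B\) relative to the unrolled derivative — a
constant absorbed by the teacher learning rate.

Two readings of the published procedure were genuinely ambiguous and are
recorded as config switches:

* `uda_on`: the consistency branch is applied to **unlabeled** images by
  default (standard practice in this training family; the pseudocode line
  literally names the labeled batch but its caption says unlabeled).
* `pseudo_mode`: "sample a pseudo-label" vs "hard label" — both exist;
  argmax is the default for stability.
* The teacher update is read as \(\eta_T \cdot (g_{\text{feedback}} +
  g_{\text{supervised}} + g_{\text{UDA}})\): all three terms are gradients
  of teacher losses, so they share the learning rate.

### Why training batches are augmented

Pseudo-labels are assigned on the *clean* view of an unlabeled image; the
student then trains on an *augmented* view of the same image, and the
teacher's supervised branch also sees augmented labeled images. This is
the noisy-student recipe: without input noise, pseudo-label training
degenerates to self-confirmation (the student reproduces the teacher's
decision boundary, including its mistakes), which we observed directly on
fixtures as confidently wrong pseudo-labels. The feedback chain
(`teacher_feedback_gradient`) uses the same augmented views the student
trained on, so `h` scores exactly the update the student took.

### Additive-margin softmax

The classifier head L2-normalizes both the embedding and each class-weight
column, producing cosine logits \(\cos\theta_j \in [-1, 1]\) (a `1e-12`
norm guard avoids division by zero on degenerate inputs). The loss
subtracts a margin \(m\) from the target-class cosine only, scales all
logits by \(s\), and applies softmax cross-entropy:

\[
L = -\frac{1}{n}\sum_i \log
\frac{e^{s(\cos\theta_{y_i} - m)}}
     {e^{s(\cos\theta_{y_i} - m)} + \sum_{j \ne y_i} e^{s\cos\theta_j}}.
\]

With \(m = 0, s = 1\) this is exactly softmax cross-entropy on the cosines
(tested to 1e-6). Margins tighten intra-class clusters and widen
inter-class gaps — useful for acne grades, which have high inter-class
similarity. The reference work adopts the loss without stating \(s\) or
\(m\); the package uses the literature defaults \(s = 30\), \(m = 0.35\),
exposed in `margin_params()`. Label smoothing 0.1 mixes the one-hot target
with the uniform distribution before the cross-entropy. Inference
probabilities are the softmax over \(s \cdot \cos\theta\) without margin;
note that at \(s = 30\) these saturate, so the 0.95 pseudo-label gate is a
high bar early in training and an imperfect calibration late — another
reason the input-noise recipe above matters.

Since the pixel intensities live in \([0, 1]\), the classifier centers its
input (\(2(x - 0.5)\)); without centering, the shared DC component
dominates every embedding and the cosine head cannot separate classes.

### Optimizers and schedules

Supervised reference runs use Nesterov momentum 0.9 with cosine decay;
semi-supervised runs use RMSProp with a linear warm-up ramp followed by
exponential decay (the published warm-up description — "gradually reduce
the learning rate" — contradicts the term "warm-up"; the standard ramp-up
is implemented). The exponential decay rate is unstated in the source
tables; it defaults to 0.97 per 1000 steps and is configurable. Weight
decay (5e-4) is applied loss-side. Gradients are clipped to a global L2
norm (`grad_clip`, default 1): the feedback coefficient is a raw inner
product of gradient vectors and spikes by an order of magnitude when the
labeled loss is momentarily high, which destabilizes the teacher without
clipping.

All table defaults (learning rates 0.3/0.125, batch sizes 8/8, dropout
0.35/0.5, UDA factor 1.0, temperature 0.8, threshold 0.95, batch-norm
decay 0.99) are the `aff_config()` defaults. They were published for an
EfficientNet-L2 backbone trained for millions of steps; the desk-scale
experiments in the tests and acceptance script use a small CNN backbone
(about 7000 parameters: three stride-2 conv/ReLU stages, global average pooling,
a 32-dimensional embedding) on 32×32 fixtures for 2000 steps, with RMSProp
learning rates 0.02, no dropout, `grad_clip = 5`, and exponential decay
0.93 per 250 steps so the run actually anneals within its budget. These
values were fixed by pilot convergence runs before the comparison
experiments and are part of the scaled study design, not tuned per seed.

## Skin segmentation

The segmenter is an encoder–decoder in the LinkNet family: an input stem
and four encoder blocks, each one stride-2 3×3 convolution with batch
normalization and ReLU, then four decoder blocks (nearest-neighbor
upsample + conv/BN/ReLU) whose outputs are fused **additively** with the
matching encoder feature maps, and a final upsample-and-convolve stage
with a sigmoid producing a per-pixel skin probability. At `width = 1` the
encoder/decoder channel pairs are exactly (64,64), (64,128), (128,256),
(256,512) / (64,64), (128,64), (256,128), (512,256); `width < 1` scales
all channels proportionally for desk-scale training (the architecture
audit test runs at full width; training tests run slim). Inputs must be
divisible by 32; `segment_and_crop()` reflection-pads arbitrary sizes and
crops the result back. The training loss is pixel-wise binary
cross-entropy (the source is silent on the loss; soft Dice is available),
the mask threshold defaults to 0.5, and non-skin pixels are zeroed rather
than cropped so downstream tensors keep their shape.

The motivating observation that living-skin pixels are photometrically
distinctive (the rPPG argument) is encoded in the fixtures as a distinct
chromatic band for skin; no temporal signal processing is implemented.

## Augmentation policy

`aa_policy()` holds the active transform set with per-transform magnitude
coefficients, plus the (N, M) pair; `aa_policy_grid()` is the full 10×10
search space. The default preset keeps the eight lesion-safe transforms
(auto-contrast 0.1, brightness 0.1, equalize 0.3, rotate 1.3, shear 0.9,
translate 0.9) and excludes color, contrast, invert, posterize, solarize,
sharpness and sample pairing (scale 0 ⇒ never sampled), because lesion
evidence is chromatically fragile and mixing creates spurious compound
lesions. The source table gives only coefficients, so the unit semantics
are fixed here per transform: strength = (M/10)·scale·max-range, with max
ranges 30° rotation, 0.30 shear, 0.33 of the extent translation, ±0.9
enhancement delta; parameterless ops (auto-contrast, equalize, invert) use
the strength as a blend weight between original and fully-applied op.
Negative coefficients in the comparison presets follow the
inverted-magnitude convention. Geometric transforms use bilinear
interpolation with reflection padding and always preserve dimensions.
Whether (N, M) was tuned per dataset is unstated; the defaults N = 2,
M = 9 follow common practice for this augmentation family.

## Metrics

One-vs-rest counts per class feed accuracy (\(N_c/N\)), precision
(TP/(TP+FP)), sensitivity (TP/(TP+FN)), specificity (TN/(TN+FP)) and the
Youden index (Se + Sp − 1). The published tables report single values for
a four-class problem without stating the aggregation; this package uses
**macro** (unweighted) means over classes, excluding classes whose
denominator is zero, and computes the Youden index from the macro Se/Sp.
Several published table cells are not internally consistent under any
aggregation (YI ≠ Se + Sp − 100 by up to 0.7), so exact reproduction of
every cell is explicitly not promised; the identity checks in the
acceptance suite use the self-consistent cells.

## De-identification

Black rectangles (0-based, half-open pixel boxes from an external CSV
manifest — a deliberate choice over a bundled face detector, keeping the
module auditable) zero the eyes/eyebrows/mouth regions; filenames are
replaced by the MD5 digest of their ASCII bytes (reference vectors from
the MD5 specification are asserted in the tests). By default the
extension is excluded from the hashed text (unstated in the source;
configurable). Output PNGs are re-encoded from pixel data, so no source
metadata survives.

## Synthetic fixtures

`gen_face_image()` renders a skin-toned ellipse on a noisy background with
a grade-dependent number of reddish Gaussian blobs (radius 2–6 px at the
reference 64×64 size) drawn on skin only, per-image skin-tone jitter,
global brightness jitter, and an optional gray occluder rectangle
(probability 0.3) that also punches a hole in the skin mask — giving the
segmenter non-trivial negatives. Grade intervals default to 0–2, 3–10,
11–25 and 26–60 lesions: disjoint, so labels are well-defined, but with
boundary counts that are genuinely hard to distinguish through the
rendering noise, which keeps the task from being trivially saturated.
Lesions are chromatic (red excess) rather than luminance marks, so the
retained augmentations do not destroy class evidence.

What the fixtures emulate: the ordinal grade structure, label scarcity,
chromatically distinctive skin, clutter/occlusion negatives. What they do
not: real lesion morphology (comedones vs pustules vs nodules), secondary
changes (scarring, pigmentation), pose/illumination structure, camera
variation, or class imbalance. Passing the end-to-end experiments
therefore shows that the training machinery behaves as designed on a
learnable ordinal task with scarce labels — not that clinical-grade
accuracy would be reached on real photographs.

## Desk-scale experiment sizes

The test and acceptance experiments use: 400-image training pools (100
per grade) at 32×32 with 10% labeled, 100 held-out images, 2000 training
steps for both the semi-supervised runs and their supervised baselines;
segmentation uses 200 training and 50 held-out pairs, a 1/16-width model
and 400 RMSProp steps. These sizes are the package's chosen study
conditions for a laptop-class single-CPU run; the comparison across five
seeds pairs each semi-supervised run with an identically-budgeted
supervised baseline on the same data and seed.

## Known limitations

* The layer engine is CPU-bound base R; it is sized for desk-scale
  experiments, not for full-scale backbones.
* The pseudo-label confidence gate inherits AM-Softmax's overconfident
  probabilities; a calibration layer would decouple the 0.95 threshold
  from the cosine scale.
* Only PNG I/O is supported.
* The feedback estimator's variance grows with the batch-mean scaling
  noted above; very small accepted batches make `h` noisy, which is why
  gradient clipping is on by default.
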