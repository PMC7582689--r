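---
title: "Two-leveled video stress detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-leveled video stress detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tsdnet)
```

## The detection problem

The package classifies short video clips of a person as *stressed* or
*unstressed*. Stress shows up in two weakly coupled channels: transient
facial expressions, and body-level action patterns (self-touching
gestures, restless hand movement). The model therefore learns a
**face-level** representation and two **action-level** representations
and fuses them.

A clip is an ordered frame sequence with a per-frame face crop, a subject
id and a binary label. Three views are derived per clip:

* **face view** — the per-frame face crops;
* **still view** — the raw frames;
* **motion view** — dense optical flow between consecutive frames,
  rendered as (dx, dy, magnitude) images so both action streams share one
  backbone input convention.

All images are resized to a common side (70 px at reference scale), then
cropped to the network input (64 px): a uniformly random window during
training, the centered window at evaluation. One window per clip is
shared across all three views so their spatial correspondence survives
augmentation. Per-channel normalization statistics are computed once from
the training fold and frozen into the run configuration; the alternative
(per-image standardization) would be insensitive to between-clip
brightness differences that carry no label information but would also
discard the fixed scale of the rendered flow images.

## Face level

1. **Key-face selection.** A binary expression classifier (backbone +
   global average pooling + softmax head) maps each face crop to `eProb`,
   the probability of being *expressive* rather than *expressionless*.
   The clip's probability argmax and argmin become the key-face pair
   (`face_e`, `face_l`); ties break to the earliest frame and the two
   indices are forced distinct. Selection runs once per clip with the
   frozen scorer on centered crops — the scorer is pre-trained, so
   selection is a fixed preprocessing step, not part of the augmentation
   path.
2. **Fine difference.** Both faces pass through one weight-shared
   residual backbone giving C×H×W maps (512×8×8 at reference scale); the
   elementwise difference `D0` is refined by a residual block
   (`D = D0 + ReLU(Norm(Conv(Conv(D0))))`).
3. **Multi-scale pooling attention.** `D` is average-pooled at kernel
   sizes 1/2/4 (configurable, 8 also supported). Each scale runs a
   convolutional attention branch — `Conv` followed by three
   `Conv(ReLU(Norm(·)))` blocks — whose output is softmax-normalized
   *over the spatial positions of each channel*, then applied with a
   residual: `AD_s = D_s ⊙ Att_s + D_s`. Flattened maps concatenate to a
   C×K matrix with `K = HW + HW/4 + HW/16` (84 at reference scale).
4. **Channel self-attention.** Rectified affine maps produce
   `Rq, Rk, Rv`; `A = Softmax(Rq Rkᵀ / scale)` row-wise over channels and
   `S = A Rv`. The scale defaults to `sqrt(C)` (the conventional scaled
   dot product); a config switch (`self_attention_scale = "as_printed"`)
   divides by `C` instead. Both variants are tested against a brute-force
   oracle.
5. **Projection.** The flattened `S` passes through a rectified affine
   layer to the length-`m` stream representation `U_fac` (`m = 20`).

## Action level

One network structure, instantiated twice with independent weights, for
the still and motion views. Per-frame backbone maps are average-pooled
over their full spatial extent into length-`d` rows (2048 at reference
scale), stacked into `F (n × d)`. **Frame attention** computes one scalar
per frame (`F' = ReLU(F W1 + b1)`), a softmax contribution distribution
(`AttF = Softmax(W2 F' + b2)`), and reweights rows with a residual
(`F̃_i = (1 + AttF_i) F_i`). An LSTM (single layer, zero-initialized
states, hidden size `d`) consumes the rows in temporal order; the final
*cell* state is projected and rectified to `U_sti` / `U_mot`.

Because `W2` is `n × n`, the frame count fed to the model is fixed per
configuration (`n_frames`); longer clips are uniformly subsampled first,
and the package computes flow between the subsampled neighbours the
model actually sees. The motion stream of an `n`-frame model uses
`n − 1` flow images and its own `（n−1)×(n−1)` attention.

## Fusion

The default integrator weights each stream by a local scalar ReLU gate,
concatenates the weighted streams into `U ∈ R^{3m}`, applies an
elementwise global gate with a residual (`G = ReLU(W11 ⊙ U + b11) ⊙ U +
U`) and classifies with a softmax layer. The elementwise reading of the
gate is a deliberate resolution of a dimensional ambiguity (a length-3m
gate weight against a length-3m input admits either an inner product or
an elementwise product; only the elementwise reading makes a length-3m
bias consistent); the scalar variant remains available via
`gate_mode = "scalar"`.

Three comparison integrators are provided: **early** (one affine+softmax
on the unweighted concatenation), **loss-based early** (early head plus
one auxiliary head per stream, total loss `Σ λ_i loss_i` with
`λ = (0.2, 0.2, 0.2, 0.4)`), and **late** (independent per-stream heads,
posteriors averaged; majority vote available). When fewer than three
streams are active the λ vector keeps its per-stream prefix and fused
tail and is renormalized.

## Training recipe

The reference recipe is SGD with momentum 0.9, weight decay 0.01, batch
size 64, 120 epochs, learning rate 0.01 halved every 15 epochs, and all
parameters initialized from U(−0.001, 0.001). The **tiny preset** — the
package's default test configuration — scales the problem to a CPU desk
run: 36-px resize / 32-px crops, 8 model frames, 32-channel backbones,
20 epochs, batch 8, learning rate 0.01 with a one-epoch linear warmup,
weight decay 1e-4, He-scaled initialization (recurrent weights at the
conventional ±1/√h), global gradient-norm clipping at 5, and a 0.1
learning-rate multiplier on the fusion gate parameters. The stability
measures address two failure modes of short-budget training observed
empirically: momentum steps early in training can push whole rectified
layers into the dead regime, and — because a stream that has not yet
learned anything is pure noise to the classifier — full-rate SGD will
close that stream's ReLU gate to reduce loss variance before the stream
becomes useful, after which the gate's gradient is identically zero.
Gates should adapt on the time-scale of whole-stream usefulness, which
changes far more slowly than the representations being gated.

Two initialization details matter beyond the preset:

* **Gate initialization.** Stream representations are non-negative
  (they are ReLU outputs), so a generically initialized local ReLU gate
  `w = ReLU(W·U + b)` can be closed for *every* input, has zero gradient,
  and never recovers — in practice this killed whole streams. Gate
  weights therefore start near zero with the local bias at 1: training
  begins from open local gates (`w ≈ 1`) and an identity global gate
  (`g ≈ 0`, `G = U`).
* **Normalization placement.** "Batch normalization" is implemented as
  per-sample, per-channel normalization over spatial positions with a
  learned scale/shift — deterministic at evaluation, exact at batch size
  one, no running state. One consequence is respected in the
  architecture: globally average-pooling a spatially normalized map
  yields a near-constant per-channel value, so the action and scorer
  backbones end with an *unnormalized* convolution stage, while the face
  backbone (whose output feeds an elementwise difference, not a pooled
  summary) keeps normalization throughout.

Model selection keeps the best-validation-accuracy epoch. Metrics
(accuracy, precision, recall, F1, row-normalized confusion matrix) treat
*stressed* as the positive class, with a macro-average option. Subjects —
never clips — are split 60/20/20 into train/validation/test by floor
arithmetic with the remainder to train, and experiments average over
independent divisions (three by default in `make_splits()`).

## The synthetic generator

Real stress-video corpora are private; the generator emulates the
*statistical structure* the pipeline depends on, with plantable signal:

* **Faces** are parametric cartoons (elliptical head, eyes, brows, a
  mouth arc) whose mouth curvature, brow raise and eye opening increase
  monotonically with an expressiveness parameter; the drawn mouth apex
  offset is `round(0.18·size·e)` pixels, so expressiveness can be
  re-measured from pixels by an independent oracle. Per-frame
  expressiveness follows a smooth bump with a unique maximum whose index
  is recorded as key-frame ground truth. The peak amplitude is
  `0.5 ± 0.45·face_signal` (upper sign for stressed clips): at
  `face_signal = 0` the face channel is label-independent by
  construction.
* **Frames** show a static torso and a moving blob whose trajectory
  interpolates between a neutral path and a class-specific family
  (hand-to-head arc for stressed, hand-to-side for unstressed) with
  weight `action_signal`, plus per-clip phase/speed jitter.
* **Subjects** carry persistent appearance offsets (head geometry, eye
  gap, shade), giving the identity structure that subject-level splits
  must respect.
* All randomness derives from per-clip substreams of one base seed, so
  any clip is reproducible in isolation; pixel noise is additive
  Gaussian (default sd 0.02, a mild sensor-noise level).

What the generator does **not** emulate: photorealistic appearance,
illumination and pose variation, face-detector failures, articulated
body motion, or the label noise of a human elicitation protocol. Passing
tests therefore demonstrate that the architecture, gradients, selection
logic and training loop are correct and that the model recovers planted
signal at desk scale — not that the reported real-data accuracies
transfer.

## Numerical choices and degenerate inputs

* Softmax computations subtract the row maximum before exponentiation.
* The spatial-normalization epsilon is 1e-5; a constant channel maps to
  its learned shift and contributes zero gradient.
* Key-face ties break to the earliest frame; under a full tie the pair
  is frames 1 and 2 (the difference map is then zero, which is valid).
* The default optical flow is integer block matching (SSD cost over a
  5×5 window via integral images, search radius 4, replicate borders,
  ties toward the smallest displacement so identical frames give an
  exactly zero field). Any `(gray_a, gray_b) -> H×W×2` callable can be
  injected instead. Textureless inputs return a finite (zero) field.
* Uniform subsampling of a length-N clip to n frames uses
  `round(seq(1, N, length.out = n))`.
* Cross-entropy adds 1e-12 inside the logarithm and training aborts with
  a diagnostic on a non-finite loss.

## Problem sizes used by the tests and the acceptance script

Unit tests run a micro configuration (16-px inputs, 4–8 channels) whose
gradients are verified against finite differences and whose operations
are checked against scalar-loop oracles. The learning experiments use
the tiny preset: 200 clips from 10 subjects for the planted-signal and
null-signal runs, a 200-clip two-population dataset (face-signal
subjects and action-signal subjects) for the fusion-benefit comparison,
and a 48-clip dataset for the ablation/integration table runners at a
reduced epoch count. The expression scorer trains on a 120–400 image
corpus. These sizes are the package's desk-scale defaults; all scale up
through the configuration objects.

## Known limitations

* The LSTM is single-layer and unidirectional; hidden size equals the
  frame-feature length.
* The attention branches' convolution kernels are fixed at 3×3,
  channel-preserving, padding 1; branch weights are not shared across
  the three applications.
* The reference preset reproduces the published tensor geometry
  (512×8×8 face maps, 2048-long frame features, m = 20, two classes)
  but its residual backbone depth is a package choice — the source
  architecture names only a residual-network family.
* Training is strictly CPU and single-threaded beyond BLAS; the tiny
  preset is the practical operating point in this form.
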