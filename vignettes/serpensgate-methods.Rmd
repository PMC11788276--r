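---
title: "Snake convolution, super-token attention and desk-scale detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snake convolution, super-token attention and desk-scale detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`serpensgate` implements a single-stage anchor-free plant-disease detector
built from three non-standard blocks — dynamic snake convolution inside a
C2f stage, spatial pyramid pooling with efficient layer aggregation
(SPPELAN), and super-token attention (STA) — wired into a 24-row
backbone/neck/head graph with export maps at strides 8, 16 and 32. This
vignette explains the science, the numerical choices, and what the
synthetic-data experiments do and do not demonstrate.

## The tensor substrate

No deep-learning framework is involved: feature maps are plain R arrays
with dim `c(H, W, C, N)`, convolutions run through C++ im2col/GEMM kernels
(RcppArmadillo), and every layer implements an explicit analytic backward
pass. The test suite verifies each backward pass against central finite
differences (tolerances around `1e-4` with step `1e-5`, the usual scale at
which double-precision central differences are trustworthy). Double
precision throughout; batch-norm statistics use the one-pass sum/sum-of-
squares form, safe at these magnitudes.

## Parameter accounting

Every block has an exactly auditable parameter count. The counting
convention, which is the only one consistent with all structurally forced
rows of the published per-layer table, is:

* convolutions inside a conv block carry no bias (the batch norm absorbs it);
* batch normalization counts its `2 c` scale/shift values, never its
  running statistics;
* the detect head's final 1×1 convolutions carry biases;
* two kinds of frozen values are counted as non-trainable: the 16-entry DFL
  projection (the integers 0…15 that turn a discrete distribution over box
  offsets into its expectation) and the two 81-entry 3×3 unfold/fold
  kernels with which the sparse super-token association can be expressed as
  convolution; together 16 + 162 = 178, exactly the difference between the
  published totals for parameters and gradients.

Four rows of the published table (the backbone C2f stages and the snake
C2f) cannot be reproduced from any published structure; the source
describes its C2f as "modified" without giving the wiring. `audit_parameters()`
therefore reports those four rows as known-unreproducible, with the printed
expectation alongside the actual count, and matches the other twenty rows
exactly. The published per-layer column in fact sums to a different number
than the published grand total; the audit keeps the two comparisons
separate rather than forcing an agreement that the source itself does not
contain.

## Dynamic snake convolution

A snake kernel of length `k` (default 3) extends from each output pixel
along one axis. A 3×3 convolution + batch norm + `tanh` predicts, per
pixel, `2k` bounded offsets: `k` morph-axis step perturbations and `k`
perpendicular drifts. Coordinates accumulate from the kernel center
outward — step `1 + offset` along the morph axis, drift `+offset`
perpendicular — so each position references the previous one and two
consecutive samples never separate by more than two pixels. This is the
continuity constraint that keeps the deformation on the lesion instead of
scattering. Sampling is bilinear with coordinates clamped to the feature
extent (replicate behaviour at borders); gradients flow to the features
*and* to the coordinates, hence to the offset predictor.

Design choices worth stating:

* **Center anchoring.** The accumulation is symmetric about the kernel
  center. Anchoring at an end would make the operator drift under
  translation; center anchoring keeps it translation-consistent, which the
  tests check at zero offset.
* **Branch normalization.** The two snake branches use group normalization
  (groups = `c/4`, affine) rather than batch norm — deformable branches see
  strongly position-dependent statistics, and group norm removes the
  batch-coupling there. This choice does not enter any audited count of the
  published rows.
* **Zero-offset limit.** With the offset convolution zeroed the morph-x
  branch is exactly a `k`×1 convolution (replicate-padded); the suite
  asserts this to `1e-5`.

`build_c2f_dysnake()` places a three-branch DySnakeConv (standard k×k conv
block, morph-x snake, morph-y snake, fused by 1×1 conv) as the second
convolution of each C2f bottleneck. Because sampling adapts to the feature
extents, the block accepts any spatial size, including odd and non-square
maps.

## Super-token attention

The `C`-channel map at the deepest stage is flattened row-major into
`N = H·W` visual tokens. Initial super tokens are means over grid cells
(default 5×5 on the 20×20 map, so `m = 16`; extents that do not divide get
ceil-sized edge cells). One sampling iteration (the default; the count is
configurable) computes:

1. a sparse association `Q`: for each token, softmax over
   `X_i · S_j / sqrt(C)` restricted to the 3×3 neighborhood of its own
   cell — at most 9 non-zeros per row, rows summing to 1;
2. the update `S = Q̂ᵀX` with `Q̂` column-normalized, so every super token
   is a convex combination of tokens (the suite checks the coordinate-wise
   convex-hull property on every iteration).

Multi-head self-attention (4 heads by default; head count does not affect
the parameter contract of `3C² + C² + C` trainable values) runs over the
`m ≪ N` super tokens, the result is mapped back through `Q`, projected,
and added residually. One sampling pass costs `19NC` flops: `NC` for the
grid means plus `9NC` each for the sparse association and the update —
`sts_complexity()` returns exactly this decomposition.

The distance-based (Gaussian-kernel) association of classical superpixel
sampling appears in the tests only as a reference point; the production
path is the attention-style softmax above. The `1/sqrt(C)` scaling is the
standard attention temperature; the source text is ambiguous between `C`
and `sqrt(C)`, and the choice affects no audited quantity.

## The assembled graph and its wiring

`model_table()` is the declarative 24-row table; `build_model()` wires it,
validates channel compatibility along every edge (a concat mismatch raises
an error naming the edge), and records strides. Three wiring details are
easy to get wrong and are asserted in tests: the attention block sits
*after* SPPELAN; the stride-16 bottom-up concat (layer 18) joins the
layer-12 concat node, not the C2f after it; and the stride-32 concat
(layer 21) joins the SPPELAN output, not the attention output. Any input
with sides divisible by 32 is accepted; export strides are always 8/16/32.

Weights initialize Kaiming-style for convolutions (no pretraining — the
reference protocol trains from scratch), batch-norm scale 1/shift 0, and
the detect head gets the usual decoupled-head priors (box bias 1, class
bias `log(0.01/0.99)`) so the background-dominated classification loss
starts calibrated.

## Losses and assignment

Assignment is task-aligned: candidates must have their anchor center
inside the ground-truth box; the top-10 by `cls^0.5 · IoU^6` are kept per
ground truth; contested anchors go to the higher alignment; class targets
are alignment scores normalized per ground truth to its best IoU. The box
loss is Wise-IoU with the published pairing α = 1.9, δ = 3, read as the
v3 focusing factor `r = β/(δ·α^(β−δ))` with outlier degree
`β = (1−IoU)/mean(1−IoU)` (running mean, gradient-detached, momentum
0.05); the enclosing-box denominator of the distance term is detached as
in the published formulation. Classification is binary cross-entropy with
the soft targets; box regression also carries the two-bin DFL
cross-entropy. Loss weights box:cls:dfl = 7.5:0.5:1.5, the conventional
detector weighting. All loss gradients are analytic and reach the head
through the DFL softmax expectation.

## The synthetic scene generator

The generator emulates the traits that make field imagery hard — several
objects per scene, elongated and twisted lesions, cluttered textured
backgrounds, lighting variation (gain 0.75–1.25), occasional occluding
strips (p = 0.3) — with six classes: three lesion types (curved brown
streak, dark blotch cluster, yellow ring spot, drawn on an unannotated
host leaf) and three whole-leaf types (broad, narrow, lobed). Streaks are
S-shaped cubic Béziers whose arc-length/chord ratio averages above 1.2, so
the curved structures the snake convolution targets are genuinely present.
Scenes are bit-exact functions of their seed, and every annotation is the
tight bound of its rendered object before occlusion, so a detector with
oracle access to the labels scores mAP@0.5 = 1 by construction — the
label-consistency check the suite runs.

What passing on this data does **not** show: robustness to real
photographic texture, to inter-class visual similarity (the classes here
are deliberately color- and shape-separable so a small CPU-trained model
can learn them), to class imbalance, or to annotation noise — all present
in real field datasets and all outside what a synthetic desk profile can
certify.

## Desk-scale training

The desk profile is 256×256 scenes, 200 training and 50 validation images
(a 250-scene dataset generated from seed 7), six classes, and a
quarter-width variant of the assembled graph (every channel scaled by
0.25, minimum 4, multiples of 4) with `reg_max = 8` distribution bins —
half the full-scale 16, matching the halved relative box extents on the
smaller canvas. Training is SGD (momentum 0.937, weight decay 5e-4 on
matrix-shaped parameters), batch 8, learning rate decaying linearly from
1e-2 to 1e-4 with a 50-iteration warmup, 30 epochs, mosaic on except the
last 10 epochs. Batch-norm running statistics use momentum 0.1 — at 25
iterations per epoch the 0.03 of long-schedule practice leaves evaluation
mode lagging far behind training mode, which shows up as near-zero mAP on
a model that predicts correctly under batch statistics.

These sizes keep a full training run in the ten-to-fifteen-minute range on
one CPU core while leaving the task learnable; they are stated here as the
package's reference experiment, and the acceptance suite runs exactly this
configuration.

## Metrics

Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)` (zero
denominators give 0 by convention; values live in [0,1], percent is a
display convention). Per-class AP uses greedy confidence-ordered matching
at IoU ≥ 0.5, each ground truth matchable once, and all-point
interpolation (precision envelope made monotone from the right, step
integration); classes absent from both truth and predictions are excluded
from the mAP mean. The published headline table contains an F1 that is
inconsistent with its own precision and recall under the harmonic-mean
formula — likely a macro-average over classes — so `evaluate_model()`
reports both the pooled F1 and a macro-averaged F1 without asserting
either as canonical. NMS is greedy, class-wise, at IoU 0.7. Everything is
cross-checked against brute-force oracles on randomized instances.

## Degenerate inputs and tie-breaks

Degenerate boxes score IoU 0 with a warning; empty label files parse to
empty annotation tables; a super token whose association column is all
zero keeps its previous value and is flagged; NMS ties break by index
after the stable descending-score order; `split_dataset()` gives the
validation split the extra item when the non-training remainder is odd
(2569 items → 2055/257/257; the published 2055/256/256 does not sum to its
own total and cannot be produced by any rounding rule).

## Known limitations

* CPU-bound and double-precision: full-scale (640², width-1) training is
  out of reach; the full model is exercised by construction, audit, and
  single forward passes.
* The four modified C2f rows are reported, not reproduced; no layout
  matching their printed counts is asserted anywhere.
* Grad-CAM explains the single best-scoring anchor's class confidence; a
  layer that does not feed that anchor's scale legitimately yields an
  all-zero map (with a warning) rather than a fabricated one.
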