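---
title: "spikeformer: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spikeformer: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeformer)
```

## The problem

Wheat spikes (the grain-bearing ears) are counted in field photographs as a
yield proxy. The objects are elongated, numerous (tens per frame), heavily
occluded and variably lit — conditions under which purely local
(convolutional) features struggle, motivating a backbone with windowed
self-attention and an anchor-free detection head. This package is a
from-scratch R implementation of that stack, exercised on synthetic scenes
because the originating field dataset is not publicly deposited.

## Backbone

An `H x W x 3` image is padded bottom/right to a multiple of 32 and split
into 4x4 patches; each patch is a 48-dimensional token (`4*4*3`). A linear
embedding maps tokens to `C = 96` channels (16 for the `tiny` variant).
Four stages at strides 4/8/16/32 follow; between stages a patch-merging
layer concatenates 2x2 token groups (4C), layer-normalises, and projects to
2C, halving the grid. Although the textual description places a merge
"after each stage", three merges (none after stage four) are the only
arrangement consistent with the published stride table `[4, 8, 16, 32]`,
and that is what is implemented.

Each stage is a sequence of block pairs:

```
z'   = MW-MSA(LN(z)) + z          z'' = SR(z')
z    = MLP(LN(z'')) + z''
z'   = SMW-MSA(LN(z)) + z         z'' = SR(z')
z    = MLP(LN(z'')) + z''
```

`MW-MSA` runs windowed multi-head attention in three parallel branches
with window sizes `X = 7, 9, 11`. Each branch is full-channel with its own
Q/K/V projection and its own relative-position bias table (one learnable
scalar per `(2X-1)^2` relative offset and head); branch outputs are
concatenated (3C) and linearly projected back to C. This literal reading
of the concatenation formula was chosen over a cheaper channel-split
design because only the full-channel form approaches the published
per-block parameter budget. Heads have dimension `d = 32` (8 for tiny), so
stage `i` uses `C_i / 32` heads per branch.

Attention within a window is `Softmax(Q K^T / sqrt(d) + B) V`. The shifted
variant (`SMW-MSA`) cyclically rolls the grid by `floor(X/2)` in both axes
per branch before windowing and rolls back after; an additive mask
(`-1e9` on forbidden pairs) keeps tokens from attending across regions
that were not contiguous before the roll, using the standard three-band
region scheme indexed by post-roll canvas position. Grids that are not
window multiples are zero-padded bottom/right; padding carries a dedicated
region id, so it can never influence real tokens (tested by comparing
against a per-token brute-force oracle that sees only real tokens).

`SR` is the spatial-reduction hook. Taken literally it would shrink the
token map inside every block, which contradicts the published per-stage
output resolutions; resolution preservation was judged the binding
contract. The default is therefore the identity, and a `bottleneck(r)`
mode is available that mixes `r x r` token blocks through a linear map and
restores the grid by replication — it reduces mixing cost without ever
changing the grid.

### Variants and parameter counts

S/B/L share channels `[96, 192, 384, 768]` and differ in depths
(`[2,2,2,2]`, `[2,2,6,2]`, `[2,2,18,2]`). `count_parameters()` gives a
closed-form count that matches the instantiated arrays exactly. Against
the published totals (42.4M / 60.1M / 100.6M including the detector), this
implementation lands within about 3% for S and 12% for B and L. Exact
agreement with all three is arithmetically impossible for any fixed
per-block cost, because the published deltas imply `(B-S)/4 = 4.43M` but
`(L-B)/12 = 3.38M` per stage-3 block; the ordering and a +-15% window are
the meaningful checks.

## Detection head and losses

The stride-8/16/32 backbone outputs feed a feature pyramid (lateral 1x1
projections, top-down nearest-neighbour sums, 3x3 smoothing, stride-2
convolutions for P6/P7; 256 channels, 32 for tiny). Two shared towers of
3x3 convolutions (four at full scale, two for tiny), each followed by
per-location channel normalisation and ReLU — the role group normalisation
plays in the reference anchor-free head — produce classification,
center-ness and box branches. Box regression predicts
`ltrb = exp(s_l * raw) * stride` with a learnable per-level scale `s_l`,
guaranteeing positive distances.

A location is a positive sample when it falls inside a ground-truth box
(boundary inclusive; the encoder treats zero distances as valid and leaves
strictness to the assigner) and its largest side distance lies in the
level's range (`(0,64], (64,128], (128,256], (256,512], (512,Inf)`).
Nested or overlapping boxes resolve to the smallest area, ties to input
order. The loss is

```
L = L_cls/N_pos + lambda1 * L_ctr/N_pos + lambda2 * L_reg/N_pos
```

with focal classification loss (`alpha = 0.25`, `gamma = 2`) over all
locations, binary cross-entropy on the center-ness of positives, and a
selectable IoU-family regression loss over positives. `lambda1 = lambda2 =
1`, following the reference settings. The regression sum is taken over
positives only: the printed formula sums over the union of positive and
negative regions, but negatives have no regression target under any
standard reading, so the term is a no-op for them; this reconciliation is
deliberate and documented rather than guessed silently.

### The WIoU loss

```
L_wiou = 1 - IoU(pred, gt) + psi * ||c_pred - c_gt||^2
psi    = 4/pi^2 * (atan(w_gt/h_gt) - atan(w_pr/h_pr))^2
```

Two properties of the printed formula are preserved deliberately:

* `psi` **multiplies** the squared center distance, so the whole penalty
  vanishes whenever the aspect ratios agree — even for distant boxes. CIoU
  adds its two penalties instead. The reduction `L_wiou = 1 - IoU` under
  equal aspect ratios is asserted in the tests as an as-printed property.
* The distance term is the **raw** squared Euclidean center distance in
  pixels, so the loss is not scale-invariant (the term grows as `s^2`
  under joint rescaling; also asserted). A `normalize = TRUE` mode divides
  by the squared enclosing-box diagonal (DIoU-style) as a training
  stability option; unit definitions and all tests use the printed form.

The unnormalised-distance reading of the norm `||Pr, Gt||` as a
center-point distance follows the surrounding text, which speaks of
minimising the Euclidean distance between central points.

GIoU and CIoU comparators are implemented for ablation parity; CIoU's
`alpha = v / ((1 - IoU) + v)` is treated as a constant during
differentiation, as in its original formulation.

## Evaluation

Metrics follow the COCO definitions exactly: greedy per-image matching at
each IoU threshold (each detection takes the highest-IoU unmatched ground
truth at or above the threshold, ignored boxes never count), global score
ordering with insertion-order tie-breaks, 101-point interpolated average
precision, thresholds 0.5:0.05:0.95, area ranges `[32^2, 96^2]` (APm) and
`> 96^2` (APl), at most 100 detections per image. APs is available behind
a flag but omitted from the default report, since spikes occupy medium and
large area ranges in practice. The implementation agrees with the
canonical COCO evaluator to 1e-6 on randomized toy datasets (frozen
reference values live in the test suite) and with an independent
brute-force evaluator written for the tests.

## Synthetic scenes: the stated world

The generator emulates what field imagery of wheat is described to
contain: 20-80 spikes per image by default (captioned real densities run
from the low twenties to the mid seventies), elongated spike bodies
(length 8-18% of the image side, length-to-width 3-5), mostly-upright
orientations (normal, sd 0.4 rad), spikelet striping along the axis, a
low-frequency textured background, a directional illumination ramp
(+-12.5% brightness by default) and unbounded mutual occlusion up to 50%
of a new spike's mask. Boxes are the exact axis-aligned extents of each
rendered spike mask; occluded spikes keep their full (amodal) box,
matching common wheat-head annotation practice. Everything derives from
one seed; identical (config, seed) pairs are bitwise reproducible.

What the generator does **not** emulate: photorealistic texture, leaves
and awns as distractors, perspective foreshortening, motion blur, and
cross-site domain shift. A green end-to-end test therefore establishes
that the architecture, losses, assignment and optimiser interoperate and
that training makes measurable progress on scenes of the stated geometry —
not that field-accurate mAP is achieved; the published full-scale scores
are explicitly out of the package's reproduction scope.

## Numerical and configuration choices

* Layer norm epsilon `1e-5`; GELU in MLPs; truncated-normal(0.02) weight
  init, zero biases; bias tables truncated-normal(0.02); classification
  bias initialised to `-log(99)` so training starts at ~1% foreground
  probability (focal-loss convention).
* Attention masks use `-1e9` (not `-Inf`) so padded windows can never
  produce NaN; padding tokens share one region id and attend only each
  other, and their outputs are cropped.
* `N_pos` is clamped to at least 1 so empty scenes yield finite losses.
* Logarithms in losses clamp their argument at `1e-12`.
* Detection: score threshold 0.05, per-level top-1000 before NMS, NMS IoU
  0.6, at most 100 detections — reference anchor-free settings, since the
  source text specifies none of them.
* Optimiser: AdamW-type (betas 0.9/0.999, decoupled weight decay 0.05).
  The published full-scale recipe (learning rate `1e-4`, 24 epochs) is the
  default for the S/B/L variants. The CPU-scale `tiny` configuration uses
  `lr = 1e-3`: a model two orders of magnitude smaller trained for 200
  iterations needs a correspondingly larger step size than the full-scale
  recipe (rates above ~3e-3 showed transient loss blow-ups and were
  rejected). Training progress is measured as the dataset-mean loss of the
  trained model against that of the untrained model, evaluated identically
  over all scenes, since per-iteration values confound progress with
  per-image sampling noise. An optional step decay (`lr_decay_at`) is
  available but off by default.
* Ties in score-based orderings break by insertion order; all orderings
  are deterministic, and single-threaded reruns reproduce loss traces
  exactly.

## Limitations

* Pure-R training is practical only at the `tiny` scale; the full S/B/L
  variants instantiate and run forward, but 24-epoch field-scale training
  is far outside CPU budgets.
* Single foreground class by default (class count is configurable but the
  synthetic world only emits spikes).
* Images are read and written as binary PPM; no PNG/JPEG codec is
  available in a dependency-free R stack, and any standard tool converts
  losslessly.
* The relative-position bias tables are independent per branch; whether
  the three branches of the multi-window block share tables is unstated
  in the source description, and independence is the more expressive
  default.
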