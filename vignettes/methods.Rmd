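---
title: "Deep-perception berry detection: model, compression and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-perception berry detection: model, compression and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mature ginseng berries grow in dense, umbrella-shaped clusters (umbels) at
the top of the plant. In canopy scenes they overlap each other and are
occluded by leaves, they appear over a wide range of scales because plant
heights vary, and illumination shifts with the shade structure above the
ridges. `yologinseng` implements a single-class detection method for this
setting: a small-width CSP (cross-stage-partial) detector whose backbone
feature extractor is upgraded with a deep-perception module, C3f-RN, and
which is subsequently compressed by BN-scale channel pruning so that the
accuracy gained by the heavier backbone does not cost deployment speed.

Everything runs on a self-contained reverse-mode tape with compiled
convolution kernels, so models are built, trained, pruned and evaluated in R
without an external deep-learning runtime. The network modules are the point
of the package, so they are implemented here rather than delegated.

## The detector

The baseline is the standard small-width CSP detector: a strided 6x6 stem,
four backbone stages (conv stride 2 followed by a C3 block of 1/2/3/1
bottlenecks at width multiplier 0.50), an SPPF pooling block, an FPN+PAN
neck, and a three-scale anchor head (strides 8/16/32, three anchors per
scale). With one class this graph has 7,022,326 learnable scalars at
train time; after folding each convolution-batchnorm pair into a biased
convolution — the deployed form that validation tools summarise — the count
is 7,012,822. `count_parameters(model, fuse_bn = TRUE)` reports the latter
convention; both are exact closed-form functions of the configuration.

## The C3f-RN module

`assemble_yolo_ginseng()` replaces each of the four backbone C3 stages by a
C3f-RN module of matching width and repeat count. The module is built from
two parallel CSP-style branches whose outputs are projected by 1x1
convolutions and summed, followed by a switchable atrous convolution (SAC)
and a coordinate-attention (CA) gate:

* **Branch one** applies a 1x1 convolution, splits the result into two
  halves of width `h = c/2`, passes one half through `n` residual
  bottlenecks — each two 3x3 convolutions with a parameter-free SimAM gate
  at the tail — and concatenates the split halves together with every
  intermediate bottleneck output (the dense CSP-fusion convention) before a
  1x1 fuse convolution. `n` is inherited from the host stage (1, 2, 3, 1).
* **Branch two** splits the same way; one half passes through a single
  residual bottleneck, the other through a 3x3 convolution and a windowed
  attention (Swin) stage. The stage embeds 4x4 patches with a strided
  bias-free convolution at the split-half width, runs two attention blocks
  (plain then shifted windows, qkv bias, per-head relative-position bias of
  size `(2w-1)^2`, two LayerNorms, a 4x MLP with GELU), and restores the
  spatial extent by nearest upsampling. Non-divisible extents are zero-padded
  on the right/bottom and cropped after reversal, so 7x7 windows work on any
  map.
* **SAC** standardises its 3x3 kernel per output channel (learnable
  per-channel scale and shift on the standardised weights, plus a bias),
  evaluates it at dilation 1 and — with a trainable kernel offset — at
  dilation 3, and blends the two responses per position through a switch
  head (5x5 average pool, 1x1 convolution, sigmoid) initialised fully on
  the dilation-1 branch.
* **CA** pools along the two spatial directions, encodes the pooled strips
  through a shared 1x1 bottleneck (reduction 32, clamped to at least 8
  channels, hard-swish), and gates the input with the two directional
  sigmoid maps.

Because heads and window size enter only through the relative-position-bias
tables, the total parameter count obeys an exact law: with four modules of
depth 2 installed, changing the head count or window size moves the total by
`8 * n_heads * (2 * win_size - 1)^2` table entries and nothing else. The
test suite asserts this law directly, and the acceptance script pins the
absolute counts. Several internal choices that the module's textual
description leaves open (the dense concatenation, the single branch-two
bottleneck, the 4x4 patch embedding, SAC without global-context convolutions)
were fixed by exact parameter-count reconstruction against the published
accounting table for this architecture family; the count acts as the
adjudicating oracle, and the configuration here reproduces all twelve
mutually consistent rows of that table exactly.

`heads_from_window()` implements the geometric heuristic for choosing the
head count: `round(sqrt(H*W / win_size^2))`, optionally snapped to a divisor
of the embedding width. It is a starting point, not a constraint — the
head count remains a configuration choice.

## Training

`train_detector()` minimises the standard composite detection loss: CIoU on
matched boxes, BCE objectness over all cells with scale balancing
(4.0/1.0/0.4), and a single-class BCE that drives the class channel to one
so decoded confidence reduces to objectness. Targets are assigned per scale
to anchors within a 4:1 aspect/size ratio and to the cell containing the
box centre plus its two nearest neighbours. The optimiser is momentum SGD
(0.937) with weight decay 5e-4 on convolution kernels only, linear warmup
over the first three epochs and linear decay to 1% of the initial rate —
the scratch-low convention. Batch statistics drive BN in training; running
means/variances (momentum 0.03) drive evaluation.

## Compression

The slimming pipeline treats the BN scale gamma as the channel-importance
signal:

1. **Sparse training** adds the subgradient `lambda * sign(gamma)` to every
   prunable BN scale (default `lambda = 0.002`), an explicit L1 penalty
   whose rate is interpretable at the equation level rather than folded
   into weight decay.
2. **Pruning** pools `|gamma|` over all prunable channels, takes the
   `r`-quantile as a global threshold (default `r = 0.8`), and removes
   channels below it together with the producing and consuming filters.
   A minimum of 8 channels per layer is always retained, and protected
   layers are untouched. Channel surgery is exact on sequential chain
   models (the `toy_detector()` family): kernels, scales and running
   statistics are sliced so the pruned graph is shape-consistent and
   forward-runnable, and removing channels whose gamma and beta are exactly
   zero provably leaves the network function unchanged (SiLU(0) = 0). For
   the composite detector graphs the coupled widths (splits, residual sums,
   attention head divisibility) place those layers under the protection
   policy rather than under surgery; the sparsity stage and the gamma
   summaries apply to every model.
3. **Fine-tuning** continues training from the pruned weights; the graph is
   frozen, so the parameter count is invariant from this point on.

`compress_pipeline()` chains the three stages and reports the four-stage
summary (AP, parameters, weight size, per-image inference time), which on
the toy test bed reproduces the qualitative signature of the method:
parameters drop only at the pruning stage and AP dips there before
fine-tuning restores it.

## Evaluation

`evaluate_detector()` follows the VOC-style protocol at IoU 0.5: greedy
confidence-ordered one-to-one matching per image, a cumulative
precision-recall curve over all detections, and AP as the integral of the
monotone-decreasing precision envelope over recall (each recall increment
contributes its envelope precision; the idealised integral does not choose
a discretisation, so the envelope scheme is fixed and documented). Headline
precision and recall are reported at the best-F1 confidence unless a
threshold is given. The decode floor for evaluation is low (0.005) so the
PR curve is swept properly even early in training.

## The synthetic scene generator

The field imagery this method family is developed on is not publicly
deposited, so the package ships a deterministic scene generator that
emulates the dataset's structure rather than its photometry: green canopy with brown soil patches, thin stems, red
berry umbels rendered as 15-40 overlapping ellipses (radius 2-6 px at the
640 reference scale) with per-umbel scale jitter (0.6-1.4x), leaf occluders
drawn over the fruit with a configurable mean occlusion fraction (default
0.3), and a global illumination gain (0.7-1.3x). One box is emitted per
umbel whose visible area is at least 10% of its unoccluded area — the
automatic counterpart of the manual annotation rule that excludes fruits
more than 90% occluded. Every scene is a pure function of its spec and
seed.

The generator reproduces the geometric difficulty of the task (density,
occlusion, scale, illumination) but not the photometric richness of field
imagery — no camera noise, no HDR, no specular highlights, no background
clutter beyond texture. Passing the training smoke tests therefore shows
that the architecture, loss, optimiser and evaluation stack are wired
correctly and can learn the task signal; it does not certify field accuracy.
The augmentations mirror the training-set expansion of the original
protocol: random rotation, translation, brightness gain in 0.5-1.5x,
simulated occlusion patches, and 2x2 mosaic concatenation, each transforming
labels consistently and dropping boxes whose surviving area falls below 10%.

## Problem sizes and numerical choices

The test suite and the worked examples run at desk scale: gradient checks
on 4-8 pixel maps, module contracts at widths 8-16, the compression test bed
on 96-pixel scenes around an overparameterised four-layer chain detector
(widths 32/32/64/64, so that half the channels suffice — the regime channel
slimming presumes), and the end-to-end smoke experiment on 200 dense
256-pixel scenes split 7:2:1 around a width-0.0625 variant of the full
four-stage architecture, trained from scratch with batch 4, learning rate
0.025 and a 12-epoch decay horizon (about 500 SGD steps; the experiment
stops early once validation AP@0.5 clears its target and carries a
wall-clock guard). Exact parameter accounting is resolution-free and uses
the full-width 640 configuration.

Two training-stability choices matter at these step counts and are part of
the package's design: detection-head biases initialise to the log-odds of a
realistic object density (and the class bias strongly positive) so early
objectness does not collapse; and running BN statistics are refreshed by a
cumulative-average pass over training batches before each validation, since
exponential running averages lag far behind batch statistics on short
schedules. Convolutions run in double precision during training — compiled
single-precision kernels exist and agree to ~1e-7 per call, but their noise
is amplified by near-degenerate channel variances early in training, which
measurably slows convergence, so they are reserved for inference-style use
via `options(yologinseng.conv_double = FALSE)`.

Numerical conventions worth knowing: all tensors are double precision;
BN normalises with batch (biased) variance and tracks running statistics
with unbiased variance; the SimAM stabiliser is 1e-4 and its spatial
variance uses `n - 1` positions; weight standardisation in SAC uses the
unbiased standard deviation plus 1e-5; attention softmax subtracts the row
maximum; shifted windows use cyclic shifts with additive -100 masks across
region boundaries; NMS breaks confidence ties by box area so results are
order-independent; FLOP accounting counts convolution and linear
multiply-accumulates times two and excludes attention score products,
normalisations and activations.

## Known limitations

* Channel surgery is implemented for sequential chains; composite graphs
  rely on the protection policy for coupled widths.
* Multi-class training is not implemented (the method is single-class).
* The synthetic generator is a structural, not photometric, stand-in for
  field imagery; reported synthetic APs say nothing quantitative about
  field performance.
* Training in R is desk-scale by design: the full-width 640-pixel
  configuration assembles and counts exactly, but training it end to end is
  outside the intended envelope.
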