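---
title: "CNATNet: model, blocks, accounting and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNATNet: model, blocks, accounting and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnatnet)
```

## The problem and the model

Dried safflower (*Carthamus tinctorius*) filaments are traded in quality
grades: premium material is bright, saturated red-orange, evenly thick and
intact, while normal-grade material is dimmer, duller and frequently broken.
Automated grading is posed as binary image classification at two granularities
— *cluster level* (densely packed bundles, the coarse judgement made on
processing lines) and *monomer level* (single isolated filaments, the fine
judgement made in precision quality control).

CNATNet is a lightweight hybrid of convolution and attention built for this
task on embedded hardware. Its backbone is a stride-2 stem convolution
followed by four stages, each a stride-2 downsampling convolution plus a
fusion block; the head maps the final feature map to class logits. Three
bespoke components can each be switched on or off, which yields the ablation
grid M1–M9 (M5 is not defined in the grid):

* **C2S2** (stages 1–2): a cascaded split-and-concatenate extractor. A stem
  convolution widens the input, the channels are split 50/50 into two
  parallel branches (odd counts give the extra channel to the first branch),
  each branch is refined by a stack of GhostBottleneck or standard
  Bottleneck units, and the concatenated branches are merged by a 1×1
  projection:
  `F_C2S2 = Merge(Concat(f1(X1), f2(X2)))`.
* **AnC2f** (stages 3–4): attention-enhanced cross-stage fusion. A 1×1 stem
  produces base features `F`; a main branch applies `n` stacked units, each
  a refinement bottleneck followed by an **ABlock** gate
  `A(F) = sigmoid(Conv1x1(F)) ⊙ F`; the output is the residual fusion
  `F + main(F)`. The sigmoid bounds every attention weight strictly inside
  (0, 1), so gating can only attenuate, and zeroing the main branch passes
  the shortcut through exactly.
* **DWClassify**: a depthwise-separable head — depthwise k×k filtering per
  channel, 1×1 pointwise mixing to the class logits, then global average
  pooling (pool-last, so the spatial cost term of the FLOP formula is
  meaningful). Its parameter cost is `C_in·K² + C_in·C_out` against
  `C_in·hidden + hidden·C_out` for the dense baseline head.

When a component is disabled, the corresponding stage falls back to the
attention-free C2f fusion block (split, stacked residual bottlenecks,
concatenation of all intermediates, 1×1 projection), and the head falls back
to the dense convolutional head (1×1 to a 1280-wide embedding, pooling,
fully connected layer). With all three disabled (variant M1) the network is
exactly the C2f-lineage classification baseline, which anchors the parameter
accounting below.

## Design choices where the architecture was open

Several structural details are not fixed by the block definitions alone;
this package resolves them as follows and treats them as the package's
design:

* **Branch count** in C2S2 is exactly two (the fusion equation is
  normative), with the split rule documented above.
* **Branch units**: GhostBottleneck in the two early stages where C2S2
  operates (ghost ratio 0.5: half the output channels are produced by a
  cheap depthwise transform of the other half), standard Bottleneck
  available via `unit_kind = "standard"`.
* **Attention granularity**: the ABlock's 1×1 convolution produces a full
  per-position, per-channel gate, not a channel-only squeeze.
* **`n_ablocks` defaults to 2** per AnC2f block and is configurable; the
  gate convolutions of stacked ABlocks do *not* share weights.
* **Main-branch content of AnC2f**: pure stacked gates cannot increase
  representational width, and the ablation grid reports the attention
  variant as the *heaviest* model; each stacked unit therefore pairs a
  non-residual refinement bottleneck (e = 0.5) with its gate. The block-level
  identity shortcut carries the residual path, which keeps the
  zero-main-branch identity exact.
* **Conv unit** = convolution → batch normalization → SiLU, the convention
  of the C2f lineage; merge and projection layers are 1×1.
* **`merge_channels`** (the C2S2 branch width) defaults to `c_out / 2`, so
  the two branches re-assemble to the block's output width.
* **DWClassify padding** is edge-replicating, so spatially constant maps
  stay constant and the head's logits are invariant to the map size for
  constant inputs; the depthwise kernel is 3×3 with no hidden dense layer.

## Scale presets and parameter accounting

The n/s/m presets follow the published classification-lineage multipliers:
depth 0.33/0.33/0.67, width 0.25/0.50/0.75, with resolved stage widths
(stem 64; stages 128/256/512/1024 before scaling; depths 3/6/6/3 before
scaling) rounded to multiples of 8 and capped at `max_channels`
(1024/1024/768).

Parameter counting follows two conventions, and the package reports both:

* **raw**: every learnable scalar of the training-time network, including
  the batch-norm scale and shift (`oracle_param_count(net)`);
* **deploy**: batch normalization folded into the preceding convolution —
  the scale merges into the weights and the shift becomes a bias, so each
  normalized convolution loses exactly `C_out` scalars
  (`oracle_param_count(net, deploy = TRUE)`).

Published architecture tables print deploy-time counts (models are profiled
fused for inference). Under that convention the M1 baseline reproduces the
published budgets exactly:

```{r params}
for (s in c("n", "s", "m")) {
  net <- build_variant("M1", scale = s, num_classes = 1000, seed = 1)
  cat(sprintf("M1-%s: %s raw, %s deploy -> %s\n", s,
              format(oracle_param_count(net), big.mark = ","),
              format(oracle_param_count(net, deploy = TRUE), big.mark = ","),
              format_millions(oracle_param_count(net, deploy = TRUE))))
}
```

The analytic formulas (`params_c2s2()`, `params_dw()`, `flops_dw()`,
`params_model()`, `flops_model()`) count convolution weights plus declared
biases only — normalization parameters are deliberately excluded, faithful
to how such formulas are conventionally written — while the enumeration
oracle counts everything; the two agree exactly in the bias-free,
normalization-free regime, which is what the equivalence tests pin down.
FLOPs are counted as multiply-accumulates (products only, no ×2). Because
the input resolution behind the published FLOP figures is not recoverable,
FLOP totals are reported by the profiler but never used as exact targets.
The full CNATNet's own budget depends on free choices (`n_ablocks`,
`merge_channels`, ghost placement), so it is a reference, not a target;
`profile_network()` prints the achieved budget per block.

## The synthetic filament benchmark

The source dataset for this task is private field imagery, so the package
ships a procedural generator that emulates its *structure*, not its pixel
statistics. Filaments are random cubic Bezier strokes with per-vertex width;
grade conditions the colour (hue/saturation/value ranges), mean width, width
jitter, curvature, and the probability of integrity breaks (alpha gaps along
the stroke). Scenes are monomer (exactly one stroke) or cluster (8–18
strokes), over clean, cluttered (desaturated blobs) or occluded (an opaque
band) backgrounds, under natural or supplementary lighting (global gain and
colour shift), at close or distant view (stroke width/length scaling). The
scenario frequencies follow the direction of the source dataset's published
strata, including its mild premium-leaning class balance (11:10).

Two cue regimes exist:

* `cue = "color"` (default): the grades' hue–saturation ranges are disjoint
  (premium hue 2–16°, sat 0.75–0.95; normal hue 30–46°, sat 0.35–0.55), so
  the classes are separable by construction. A deliberately trivial
  hue-threshold baseline (`hue_baseline_accuracy()`) exceeds 90% on a
  default dataset, certifying that any network failure is the network's
  fault, not the data's.
* `cue = "structure"`: both grades share one colour range and differ only in
  localized integrity cues — normal-grade filaments are fragmented
  (dash-like gaps over the whole stroke), irregular in width, and carry
  small dark oxidised blemish spots; premium filaments are continuous,
  even and unblemished. The hue baseline performs at chance here (its
  saturation/value mask excludes the dark spots, and the stroke colours are
  shared), so classification requires detecting localized spatial features.
  This regime is what the behavioural ablation check uses, since localized
  cues are where spatial attention can plausibly help. Because integrity is
  inherently a monomer-level cue (overlapping strokes in cluster scenes
  bridge and mask the defects), the ablation benchmark uses monomer-only
  scenes under the controlled scenario (`p_monomer = 1`,
  `scenario = "controlled"`: clean background, natural light, close view),
  isolating the cue from acquisition nuisance that a 112-image train split
  cannot marginalise.

Determinism: a dataset is fully determined by its configuration. Per-image
seeds are derived from the master seed by the documented counter scheme
`(seed mod 94906249)·131 + 2·i`, so records are order-independent and below
the 32-bit integer limit. Splits are 7:2:1 by largest-remainder rounding,
exact globally (1000 images give 700/200/100) and stratified so every
grade × level cell appears in every split; the split path sets are disjoint.

What passing on this benchmark does **not** show: robustness to real
safflower variation (pigment chemistry, moisture, camera noise, true 4K
acquisition), since none of those are modelled. The generator's defaults are
stated in its configuration and are not claimed to match real safflower
statistics.

## Training pipeline and desk-scale experiment sizes

Training uses Adam (learning rate 0.001), batch size 32, cross-entropy, and
300 epochs by default, matching the reference configuration. Augmentation
(random rotation, horizontal flip, brightness, small affine warps; exact
quarter-turn rotations are exact pixel permutations, other geometry is
bilinear with background fill) is applied to the train split only.
Everything is seeded: builds, shuffling, augmentation draws; two runs with
the same seeds produce identical loss trajectories. The best
validation-accuracy epoch is checkpointed, and checkpoints round-trip
through `save_checkpoint()`/`load_checkpoint()` to identical metrics.

The package's desk preset — used throughout the tests so the whole suite
runs on one CPU core — is 64×64 inputs, the width-0.25 (`n`) preset with 2
classes, up to 30 epochs, on the default 160-image dataset (112 train / 32
val / 16 test; the validation split is sized so its accuracy granularity,
1/32 ≈ 3%, is finer than the 5% band the sanity check uses). Under this
preset the full model reliably reaches ≥ 95% validation accuracy within a
handful of epochs on the colour-cue dataset, and training stops early once
the target accuracy is reached. The full 224-px, 300-epoch regime remains
available through the configuration objects.

Numerical details worth knowing: batch-norm uses batch statistics in
training and running statistics (momentum 0.1, eps 1e-5) in evaluation.
Because the exponential running average lags the moving weights badly over
short runs, `calibrate_bn()` re-estimates the running statistics from the
train split (cumulative mean of batch statistics, weights untouched) before
every validation pass and hence before any checkpoint — without this, early
validation accuracies are systematically understated. Further:
weights are Kaiming-normal initialised; the softmax is computed with the
max-subtraction stabilisation; gradients of every layer are hand-written and
verified against central finite differences (relative error < 1e-6) in the
test suite. Latency (`measure_latency()`) is total inference time over
sample count with warm-up passes excluded — it is logged as informational
only and never asserted, being hardware-bound.

## Known limitations

* The generator is a stand-in: claims about real safflower imagery are out
  of scope.
* The "order" of the stacked attention mechanism is implemented as plain
  stacking of gate units; no other semantics are claimed.
* The FLOP convention (MACs, products only) and the deploy-time parameter
  convention are choices, documented above; profilers using other
  conventions will differ by the corresponding factors.
* The CPU implementation favours clarity and exactness over speed; it is not
  intended for 224-px, 300-epoch training runs, although they are expressible.
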