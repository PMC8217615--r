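---
title: "Classifying longitudinal bacterial fission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying longitudinal bacterial fission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most rod-shaped bacteria divide transversely: the cell elongates and a
septum forms across the short axis. A few taxa — notably the ectosymbiont
*Candidatus* Thiosymbion — divide **longitudinally**: the cell widens
instead of elongating, and the division furrow runs along the long axis.
Counting such cells in phase-contrast micrographs is a binary
classification problem per cell: *longitudinal division* (class 0) versus
*other division* (class 1). Doing this by eye over thousands of cells is
the bottleneck this package removes.

`longfission` implements the whole workflow:

1. **synthesis** — generate phase-contrast-like images with known per-cell
   labels and boxes (`generate_dataset()`);
2. **extraction** — binarize, label connected components, discard small
   areas, bounding-box each cell, export crops (`extract_cells()`);
3. **partitioning** — stratified train/validation/test splits
   (`split_class()`, `assign_splits()`);
4. **training** — a ResNet-18 binary classifier fitted with minibatch SGD
   with momentum, optionally fine-tuned from a pretrained checkpoint
   (`fission_train()`, `pretrain_network()`);
5. **evaluation** — confusion matrices and precision/recall/F1
   (`metrics_report()`).

## The classifier

### Convolution

A convolution layer sweeps a $k \times k$ kernel over the image left to
right, top to bottom at a fixed stride; each output pixel is the inner
product of the kernel with the receptive region beneath it (the map of
responses is the *feature map*). `convolve2d_valid()` exposes exactly this
primitive for a single kernel; inside the network the same operation is
performed for stacks of kernels via an im2col expansion and one BLAS
matrix product per layer. The convention is cross-correlation (no kernel
flip), as in all deep-learning frameworks.

### Residual blocks

Very deep stacks are reformulated as residual learning. A block computes

$$y = x + f(x, w),$$

where $f$ is two 3×3 convolution + batch-norm layers with a ReLU between
them, and the skip connection carries $x$ forward unchanged. If the
optimizer drives $w$ to zero, the block degenerates to the identity
$y = x$, which is what makes depth cheap to add. When a stage halves
resolution and doubles width, the skip path uses the standard 1×1
strided projection convolution with its own batch norm (option B); the
sketch-level architecture leaves this open and we pick the common choice.
`residual_block_forward()` returns $x + f(x,w)$ exactly (the network
applies the usual ReLU *between* blocks, so the zero-weight identity
holds at block level).

The full topology (`build_network()`) is standard ResNet-18: a 7×7/2 stem
with 3×3/2 max pooling, four stages of two blocks with widths
64/128/256/512, global average pooling, and a 2-way fully connected head.
A `width_mult` argument scales all stage widths so that desk-scale CPU
experiments (width 0.25 ≈ 700k parameters) use the same code path as the
full network. Initialization follows the usual conventions: He-normal
(fan-out) for convolutions, uniform $\pm 1/\sqrt{\text{fan-in}}$ for the
head, $\gamma = 1, \beta = 0$ for batch norm.

### Optimizer

Training minimizes 2-class cross-entropy on the head scores with
minibatch stochastic gradient descent with momentum:

$$v_{t+1} = \mu v_t + \alpha \tfrac{1}{|B|}\sum_{i \in B}
  \nabla_\theta J(X^{(i)}, \theta_t), \qquad
  \theta_{t+1} = \theta_t - v_{t+1},$$

with no dampening, no Nesterov correction and no weight decay. An epoch
draws the $N$ training items without replacement in shuffled minibatches
of 16. Every `period` epochs the learning rate undergoes the substitution
$\alpha \leftarrow \gamma\alpha$ (`lr_schedule()`); the fine-tuning
defaults are $\alpha_0 = 0.001$, $\mu = 0.9$, period 7, $\gamma = 0.1$,
25 epochs. `sgd_step()` implements the velocity form verbatim on plain
vectors — the trainer applies the identical update per parameter tensor.

### Compensated accumulation

Epoch-level loss sums use a compensated (Kahan) accumulator: alongside
the running sum $S$ a residual $R$ records the rounding error of each
addition and feeds it back into the next,

$$T = S;\quad U = x + R;\quad S \leftarrow T + U;\quad
  R \leftarrow U - (S - T).$$

This yields double-precision-like totals even in single precision;
`sum_single_precision()` demonstrates the effect in genuine 32-bit
arithmetic, and a `use_kahan` flag in `train_config()` controls whether
training averages use it (they do by default; with double accumulators
the effect is cosmetic, which is why it is a flag and not a hard-wired
choice). Note that the plain recursion does not survive every adversarial
ordering — a large term that cancels *before* the residual has been
reabsorbed (e.g. `c(1e8, 1, -1e8)`) still loses the small addend; curing
that requires the Neumaier variant, which is out of scope here.

## Transfer learning

The intended use fine-tunes from a checkpoint pretrained on a large
generic image corpus. Offline, the package ships none; instead
`pretrain_network()` *self-pretrains* the same backbone on an auxiliary
four-class synthetic shape task (narrow/wide rods crossed with septum
presence, rendered at higher noise and cropped/stretched exactly like
pipeline crops so the input statistics match). Pretraining runs at 64 px —
every layer up to the global pooling is convolutional, so the filters
transfer unchanged to 128-px fine-tuning at a quarter of the cost — with
its own optimizer settings (lr 0.003, period 10, γ 0.3, 24 epochs),
appropriate for from-scratch training. `load_pretrained()` then copies
every layer except the head, re-initializes a 2-way head, and leaves all
layers trainable (full fine-tuning; the paired epoch timings of pretrained
and non-pretrained runs imply full backpropagation rather than a frozen
backbone). The checkpoint records its normalization constants so
fine-tuning matches them; fine-tuning from an externally trained
checkpoint defaults to the ImageNet channel statistics instead.

## Augmentation and partitioning

Each crop is resized to 128 × 128 (bilinear), then — in training mode
only — rotated uniformly in ±180° (corners filled with the image median,
i.e. background), flipped horizontally and vertically with probability
0.5 each, replicated to 3 channels, and normalized per channel.
Validation and test use resize + normalization only, so reported metrics
are deterministic; a pipeline that augmented at test time could not
report a reproducible accuracy.

Partitioning holds out 33% per class for testing, then splits the
remainder 80/20 into training and validation. Held-out counts use the
ceiling; this convention is an inference, verified by the fact that it
reproduces all six published per-class subset sizes (1,202/301/741 and
6,884/1,722/4,240 from class totals 2,244 and 12,846) for every seed.
Splitting is stratified per class; subset sizes depend only on the class
size, membership only on the seed.

## The synthetic generator

The generator emulates what matters for this pipeline and nothing more:
dark capsule-shaped cells on a light noisy background (the phase-contrast
convention; an `invert` flag covers the opposite dialect), one class per
image, several cells per image, no overlaps (placement is rejection
sampling with bounded retries — the extraction step treats touching cells
as one component, which would corrupt labels).

Class geometry (see `default_class_geometry()`):

* **longitudinal_division** — width/length ratio 0.58–0.75 (dividing
  cells widen), always with an axial septum drawn as a lighter line along
  the major axis;
* **other_division** — ratio 0.25–0.42; plain rods, rods with a
  transverse septum (50%), or rods with a narrow transverse crease (25%)
  — the adversarial morphology that a classifier is most tempted to call
  a longitudinal split.

Septum gray level is capped well below any plausible binarization
threshold so a cell's mask stays one connected component, and the crease
leaves a joined core for the same reason. Cell orientations are sampled
from bands 15°–75° and 105°–165°. This is deliberate: classification
operates on tight bounding-box crops resized to a fixed square, and for a
near-axis-aligned rod that resize degenerates (a 15 × 60 box stretched to
128 × 128 turns a narrow rod into a full-frame blob whose apparent major
axis can flip, exchanging the two classes' signatures). Within the bands
the stretch factor stays below the cells' elongation and the morphology
survives the transform. No pixel size or magnification is imposed —
geometry is chosen for separability, not photometric fidelity, and the
generator makes no attempt at phase-contrast optics (halos, shade-off) or
3-D effects.

What passing on this data does and does not show: it validates the
mechanics (extraction recovers planted cells; the network can learn a
morphology distinction under the stated augmentation and budget;
pretraining accelerates convergence). It does not certify accuracy on
real micrographs, whose noise structure, debris, focus gradients and
touching cells the generator does not model.

## Extraction

`binarize()` thresholds at Otsu's histogram threshold by default (the
in-house tool this step mirrors leaves its method unstated; Otsu is
parameter-free and standard for bimodal microscopy histograms), with a
fixed-value override and an error directing users to it for constant
images. `label_components()` labels contiguous foreground under
8-connectivity by default (4 as an option), ids in raster-scan order of
first pixel. `bounding_boxes()` ignores components below `min_area`
(default 50 px², "selected a priori" in the source procedure's spirit)
and returns tight, 0-based, half-open boxes. Crops keep original
grayscale intensities — binarization is used only to localize — padded by
2 px and clipped at image borders. Touching cells become one crop; no
watershed separation is attempted, and that is a known limitation.

## Numerical and engineering choices

* **Two engines, one contract.** `R/nnmodel.R` holds a layer-by-layer
  double-precision reference implementation (used by the unit tests and
  gradient checks); `src/resnet_engine.cpp` fuses the whole
  forward/backward/update step per minibatch in single precision with
  BLAS `sgemm`. The test suite asserts the two agree to float tolerance
  on identical inputs, and training accuracy is unaffected — CNN training
  in float32 is the field norm.
* **Threading.** On load the package pins BLAS to one thread unless the
  user has chosen otherwise; runs are then bit-reproducible given the
  seed, and skinny-matrix products avoid dispatch overhead.
* **Ties.** `predict()` breaks exact score ties toward the lower class
  index; best-model selection keeps the earliest epoch among equal
  validation accuracies.
* **Degenerate metrics.** Precision with no predicted positives, recall
  with no actual positives, and F1 with $P + R = 0$ are all defined as 0;
  F1 is 1 exactly when there are neither false positives nor false
  negatives. Percentages print at four decimals with half-even rounding.
* **Batch norm.** Biased variance, $\epsilon = 10^{-5}$, running-stats
  momentum 0.1; evaluation uses running statistics.
* **Problem sizes.** Examples and tests run the width-0.25 backbone on
  200 synthetic crops per class for 10 epochs — the scale at which the
  whole pipeline, including three-seed replication, fits comfortably on a
  single CPU while still exercising every stage. The full-width network
  and 25-epoch schedule remain the defaults for real use.

## Limitations

* Touching or overlapping cells are segmented as one object.
* The generator's realism is deliberately limited (see above); accuracy
  numbers on synthetic data are mechanics checks, not biology.
* Single split (no k-fold); the split fractions reproduce the published
  sizes but membership is seed-dependent.
* The self-pretrained checkpoint is a stand-in: it demonstrates and
  tests the transfer-learning path, not ImageNet-grade features.
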