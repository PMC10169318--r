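---
title: "Methods: residual skip features, SVM heads and model stacking for granule detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual skip features, SVM heads and model stacking for granule detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulenet)
```

## The task and the three models

Transmission electron micrographs of renal biopsies are read for
electron-dense granules: dark, osmiophilic immune-complex deposits whose
presence supports immune-mediated nephritis. granulenet frames this as
binary image classification (Positive = deposit present) and implements
three classifiers that share one residual feature extractor:

* the **conventional model**, a five-stage ResNet-50-style trunk whose
  global-average-pooled stage-5 activations feed one fully connected
  layer with a softmax over the two classes;
* the **improved model**, which taps the trunk twice — the stage-2 map
  carries fine, local texture (a deposit is a small dark blob), the
  stage-5 map carries coarse, global context — flattens and concatenates
  the two maps, and classifies the vector with a soft-margin SVM;
* the **multi-model**, a stacked ensemble: a 2-input, one-hidden-layer
  ANN that maps the pair (improved score, conventional score) to the
  final probability. Both base-model scores are continuous values in
  (0, 1) — the SVM decision value through a logistic link, and the
  softmax P(Positive) — because hard labels would reduce the combiner to
  a four-entry lookup table.

## Residual blocks and the skip concatenation

Both residual units run the bottleneck main path
`1×1 → BN → ReLU → 3×3 → BN → ReLU → 1×1 → BN` and differ only in the
shortcut: the identity block adds the input unchanged
(`H(x) = ReLU(F(x) + x)`), while the convolutional block projects it
with a strided 1×1 convolution plus batch norm
(`H(x) = ReLU(F(x) + Ws x)`), allowing channel and resolution changes.
Stage 1 is a 7×7/stride-2 convolution with 64 kernels, batch norm, ReLU
and a 3×3/stride-2 max pool; stages 2–5 hold one convolutional block
plus 2, 3, 5 and 2 identity blocks with bottleneck filters
[64,64,256], [128,128,512], [256,256,1024] and [512,512,2048]. With a
224×224×3 input the stage outputs are [56,56,64], [56,56,256],
[28,28,512], [14,14,1024] and [7,7,2048], so the improved model's
feature vector has length 56·56·256 + 7·7·2048 = 903,168.

Two scales are built from one topology. `backbone_spec("full")` is the
layout above; `backbone_spec("tiny")` divides every channel count by 8
and takes 64×64 inputs, preserving the stage structure and the stage-2
skip so that every structural property exercised in tests transfers.
The tests and the shipped pipeline default to tiny; full scale is
exercised for the shape contract (a single forward pass, a few seconds
of CPU).

Numerical choices worth knowing:

* Convolutions are evaluated by **im2col lowering**: every receptive
  field becomes a row of a patch matrix and the layer is one BLAS
  product. Padding is zero-fill, sized (3 px for the 7×7 stem, 1 px for
  3×3 bottlenecks and the pool) so the printed shapes are met exactly.
* **Batch norm always runs in inference mode** with frozen statistics
  (identity at initialization), which makes feature extraction
  deterministic: the same image yields bit-identical features regardless
  of batch composition or dataset order.
* **Flatten order** is R's native column-major array order (rows
  fastest, then columns, then channels), stage 2 before stage 5. Any
  fixed order works; this one is documented and stable so stored SVM
  models remain valid across sessions.
* **Initialization** is seeded He-normal. The original training recipe
  fine-tunes a pretrained trunk; no weight archive ships with this
  package, so `build_backbone(init = "pretrained")` fails with an
  explicit message and seeded random initialization is the supported
  path. Consequently the trunk is a *frozen random projection* — a
  deliberate design: the package's claims are about architecture,
  optimization and protocol correctness, and the synthetic task is
  constructed to be separable from such features (see below).

## Training the heads

Because the trunk is frozen, the conventional model trains only its
softmax layer: hand-coded minibatch Adam (β₁ = 0.9, β₂ = 0.999) on
cross-entropy, batch size 16, 10 epochs, seeded shuffling.
`train_config()` keeps the reference configuration (Adam, cross-entropy,
10 epochs, learning rate 1e-5) as its defaults, but that rate is sized
for fine-tuning a pretrained network; a randomly initialized head needs
a head-scale rate, and the pipeline passes 0.05. With standardized
pooled features this reaches ≥ 0.9 training accuracy within the 10
epochs on the low-noise synthetic task.

The SVM head standardizes each feature dimension (statistics from the
training cohort only — raw deep activations vary over orders of
magnitude), then solves the soft-margin dual via libsvm's SMO. The
kernel defaults to RBF with the γ = 1/(d · mean variance) heuristic
(≈ 1/d after standardization); linear and polynomial kernels are
selectable. C defaults to 1. The fitted model stores the support-vector
expansion explicitly, and `svm_dual_diagnostics()` re-verifies
`Σ αᵢyᵢ = 0` and `0 ≤ αᵢ ≤ C` on demand; the test suite checks the dual
objective against an independent pairwise-SMO oracle on toy problems.

The combiner is a 2–4–1 sigmoid network trained by full-batch gradient
descent on cross-entropy (learning rate 2, at most 2000 epochs, early
stop after 25 epochs without improvement, seeded initialization). Width
4 is the smallest hidden layer that comfortably realizes nonlinear
two-input logic; the AND-gate test pins that capability. The combiner
only ever sees the stacking cohort — cohort disjointness is asserted on
every split.

## The synthetic corpus

Clinical TEM data cannot be redistributed, so `generate_image()` emulates
the structure the classifier must learn, with no claim of biological
fidelity:

| parameter | default | meaning |
|---|---|---|
| `image_size` | 224 px | square image side |
| `n_granules` | 3–8 | deposits per positive image |
| `granule_radius` | 5–12 px | equivalent radius of each deposit |
| `granule_intensity_drop` | 0.65 | fractional darkening inside deposits |
| `background_texture_scale` | 16 px | correlation length of the background |
| `noise_sd` | 0.05 | additive pixel noise (gray levels) |

The background is Gaussian-filtered white noise squashed through tanh so
it stays within ±0.12 of mid-gray 0.55 — deposits must remain the only
near-black structure. Membrane-like curves (smoothed random walks,
darkened by 0.1) give micrograph-like curvilinear texture and serve as
anchors: deposit centers are sampled along them, echoing how deposits
track membranes in real tissue. Deposits are filled rotated ellipses
with Gaussian-blurred edges, rejection-placed so no two masks touch —
hence the internal noise-free mask has exactly one connected component
per deposit, which is what the radius-measurement oracle in the tests
relies on. Sampled radii are inset by half a pixel so the rasterized
equivalent radius stays inside the declared range despite pixelation.
Per-sample seeds are integer-mixed from (master seed, index, label), so
a corpus is bit-reproducible and independent of generation order.

What the generator does **not** emulate: electron-optical contrast
physics, staining variability, tissue-type context (subepithelial vs
mesangial deposit patterns), focus gradients, or any patient-level
correlation between images. Passing tests therefore demonstrate that the
architecture, optimization and protocol are correct and that the models
learn this controlled task — they say nothing quantitative about
clinical performance, and the reference AUROC values reported on real
patient data are explicitly out of reach without that data.

The built-in learnability control: `blob_count_classifier()` (blur,
threshold at 0.3, count dark components) scores ≥ 95% at the low-noise
defaults. A deep model that cannot match a blob counter on its own
synthetic task would indicate a defect, and the tests enforce this.

## Protocol and evaluation

`run_pipeline()` mirrors the reference protocol: a stratified seeded
split into base-training / stacking / validation cohorts (reference
geometry 374/352/184 of a 910-image corpus; desk-scale default 60/40/40
of 140 tiny images), base models trained on cohort 1, the combiner on
cohort 2's score pairs, and a three-way comparison on cohort 3. The
report contains per-model confusion matrices, the raw and 2-dp metric
table (recall, precision, F1, accuracy, AUROC), ROC CSVs and a plot
with the random-guessing diagonal. Zero-denominator metrics raise
errors rather than returning silent zeros, so degenerate evaluation
sets abort the run visibly. The ROC sweeps every distinct score as a
threshold (positive when score ≥ threshold, ties sharing one point),
prepends (0,0), appends (1,1) and integrates trapezoidally; this equals
the pairwise-concordance statistic, which the tests verify exhaustively.
An automatic audit recomputes every reported metric from the emitted
confusion counts on each run.

Two consistency caveats inherited from the reference results are worth
recording. First, "accuracy" is reported both as (TP+TN)/N (58% for the
conventional model) and, in the per-model table, as F1 — the package
emits both, labelled distinctly. Second, the published multi-model F1 of
0.88 is the harmonic mean of the pre-rounded precision (0.92) and recall
(0.85); computed at full precision from its own confusion matrix the
value is 0.886, which rounds to 0.89. The tests assert the
full-precision value and reproduce the 0.88 only via pre-rounded inputs.

## Problem sizes and limitations

The shipped defaults are sized for a single CPU: tiny-scale backbone,
140-image corpus, 40-image validation cohort (the desk-scale pipeline
completes in under ten seconds; the full test suite in about a minute).
Known limitations: no fine-tuning of the trunk (no autodiff is
implemented, by design); no probability calibration of the SVM beyond
the logistic link; binary labels only; no patient-grouped splitting
validation (the option exists structurally but there is no reference
grouping to validate against); and ROC confidence intervals are out of
scope.
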