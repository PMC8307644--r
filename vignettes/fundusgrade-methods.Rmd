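---
title: "Methods: attention-gated compact bilinear grading of fundus images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-gated compact bilinear grading of fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Diabetic retinopathy grading assigns a fundus photograph one of five
ordinal grades (0 = normal … 4 = proliferative). Two properties make it
hard: the task is fine-grained — adjacent grades differ in small lesions,
not in global appearance — and real screening data is heavily long-tailed,
with grade 0 dominating and the severe grades rare. The package combines
three mechanisms aimed at exactly these properties.

**Two-stream bilinear fusion.** Two convolutional backbones (by default
architecturally different — the non-homologous configuration) produce
feature maps; at every spatial position the outer product of the two
streams' channel vectors is accumulated, so the descriptor carries
second-order channel co-occurrence statistics rather than first-order
averages. The exact descriptor `B(X) = Σ_s x_s x_sᵀ` has C₁·C₂ entries; we
never materialize it during inference. Instead, `compact_bilinear_pool()`
applies a Tensor Sketch: each stream owns a frozen Count Sketch (a seeded
hash into `d` buckets plus Rademacher signs), and the two sketches are
combined per position by circular convolution, computed in the frequency
domain in `O(d log d)`. Over projection draws the sketched inner product is
an unbiased estimate of `⟨B(X), B(Y)⟩`, with relative error shrinking
roughly like `1/√d` — the acceptance suite measures this directly against
the exact-pooling oracle.

**Channel attention.** Before fusion each stream is gated by a
squeeze-and-excite module: global average pooling, a bottleneck fully
connected layer with ReLU (reduction ratio `r`), a second fully connected
layer, and a sigmoid. The resulting per-channel weights in (0, 1) rescale
the map channel by channel, letting the model emphasize lesion-carrying
channels. The gate preserves shape, so it composes freely between backbone
and pooling.

**Complement cross entropy.** The training objective is

&nbsp;&nbsp;`L = H(y, ŷ) + γ/(K−1) · C(y, ŷ)`,

where `C` is the mean Shannon entropy of the predicted distribution
restricted to the incorrect classes (non-target mass renormalized by
`1 − ŷ[g]`). `C` is maximal, `log(K−1)`, exactly when the wrong-class mass
is uniform; pushing it up makes the classifier non-committal among wrong
grades instead of defaulting to the majority grade, which is the mechanism
that protects rare grades without reweighting or resampling.

## The sign of γ

The combined objective is written as a *sum* with an adjustment factor γ,
while the stated intent is that the optimizer should *maximize* the
complement entropy. A positive γ in a minimized sum would do the opposite.
We resolve this by defaulting to `γ = −1`: minimizing `L` then minimizes
cross entropy while maximizing complement entropy, matching the intent and
the established complement-objective convention. A positive γ remains
selectable (`loss_config(gamma = ...)`) for literal-sum replication, and
`γ = 0` reduces exactly to cross entropy (asserted to machine precision in
the tests).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 8192 (256 in desk-scale runs) | sketch dimension; error ~ `1/√d`, memory ~ `d` |
| `r` | 16 (4 for tiny backbones) | attention bottleneck reduction; smaller r = wider gate |
| `γ` | −1 | weight/sign of the balanced complement entropy |
| `epsilon` | 1e−7 | clamp floor for `log` and `1/(1−ŷ[g])` |
| `focal_gamma`, `focal_alpha` | 2, 1 | focal-loss baseline parameters |
| `learning_rate`, `momentum` | 0.01, 0.9 | momentum-SGD settings |
| `epochs`, `batch_size` | 20, 32 | desk-scale training budget |

The training hyperparameters (SGD, momentum 0.9, learning rate 0.01, 20
epochs) are the package's own defaults for the tiny configuration; no
optimizer schedule is inherited from elsewhere. Attention parameters are
per-stream (unshared) except in the homologous configuration, which shares
backbone and gate; biases in the gate are off by default (the gate is a
pure weight product) and switchable on.

## Numerical choices

- **Post-pooling normalization.** Compact descriptors pass through an
  elementwise signed square root and L2 normalization before the
  classifier (`normalize_descriptor()`, switchable off). This is standard
  practice for bilinear features: it tames bursty components and puts
  descriptors on a unit sphere. The signed square root is non-smooth at 0;
  the backward pass uses `1/(2√|e| + 1e−8)`, and the model-level
  finite-difference test disables normalization to stay away from this
  non-smoothness (the loss-level gradients are checked with it untouched).
- **Stream alignment.** Different backbones emit different grid sizes; both
  maps are adaptively average-pooled to the elementwise smaller grid
  (windows `[⌊(i−1)H/H′⌋+1, ⌈iH/H′⌉]`), a parameter-free, deterministic
  choice checked against a direct window-mean oracle.
- **Accumulation over positions is a sum, not an average**, so descriptor
  scale carries spatial support; the subsequent normalization removes
  overall scale.
- **Ties in argmax prediction** go to the lowest grade index.
- **Clamps:** `ŷ[g]` is clamped to `≤ 1 − ε` before forming the complement
  renormalization, `p log p` is 0 at `p = 0`, and cross entropy clamps its
  log argument to `[ε, 1]`.
- **Seeding.** Every stochastic component (projection tables, weight
  initialization, dataset rendering, splits, batch shuffling) draws from
  seeds derived deterministically from a single user seed via a fixed
  mixing rule, so datasets are bit-identical and training histories exactly
  reproducible across runs.

## The synthetic data generator

The generator emulates the two properties of real fundus collections the
model targets, and nothing else. Each image is a dark surround, a circular
retinal field with radial shading, a bright optic disc, and 2–4 curved
vessel strokes; lesions come from three parametric archetypes — small dark
dots (microaneurysm-like), irregular dark blobs (hemorrhage-like), bright
patches (exudate-like) — with Poisson counts around per-grade means that
are zero at grade 0 and strictly increasing in grade (defaults: totals 0,
4, 10, 18, 28). Default class counts `c(1400, 130, 280, 45, 45)` follow a
65:6:13:2:2 long-tailed profile, giving ≈1,500 training and ≈400 test
images at the default 0.21 split — the study conditions used by the
end-to-end acceptance checks, with 32×32 images, `d = 256`, two distinct
tiny backbones and 20 epochs, sized to run on a single CPU.

What the generator does *not* emulate: camera and illumination variation,
anatomical diversity, lesion texture, inter-grader label noise, and the
ambiguity of adjacent grades. A nearest-centroid baseline on two pixel
statistics separates grade 0 from grade 4 with ≥90% accuracy, so the labels
are learnable by construction. Passing the end-to-end tests therefore shows
that the architecture, gradients, losses and training loop work and that
CCE's minority-grade mechanism behaves as designed under a controlled long
tail — not that the model would reach any particular accuracy on real
fundus photographs.

## Backbone families

The `tiny` family (stride-2 3×3 conv + ReLU stacks; the two default streams
use depth 2 / 8 channels and depth 3 / 12 channels, so the streams are
genuinely non-homologous and exercise grid alignment) supports the full
backward pass and is what every experiment here uses. The `resnet50` and
`densenet121` families are normalization-free re-implementations of the
standard bottleneck-residual and dense-block layouts built from the same
conv primitives; they are random-initialized, construction- and
inference-only (no pretrained weights are distributed), and exist so the
full-scale architecture can be instantiated and probed offline. Training
them in pure R is out of scope.

## Known limitations

- Pure-R training limits practical scale to the tiny family and ~10³
  images; there is no GPU or multi-core path.
- Complement-entropy benefits are modest when the rare grades have only a
  handful of test images; with the default tail (45 images per rare grade,
  ~9 in the test split) minority recall is frequently 0 for both CE and
  CCE at desk scale, and the acceptance property is stated as a ≥
  comparison for that reason.
- The checkpoint parameter archive uses R serialization (`.rds`) with a
  JSON sidecar; only the sidecar is portable across languages.
- PNG export quantizes images to 8 bits; round-trips through disk are
  exact only to 1/255.
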