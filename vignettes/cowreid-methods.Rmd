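---
title: "Methods: multi-branch embeddings for cattle face re-identification"
author: "cowreid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-branch embeddings for cattle face re-identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Herds change: animals join, leave, and move between farms. A closed-set
classifier over known individuals must be retrained for every change, so
individual identification is better posed as *open-set re-identification*:
learn an embedding on one population, then recognize a disjoint population
by ranking gallery images against a query by similarity. Cattle faces make
this hard in a specific way — individuals share a common facial layout and
differ mainly in their two-tone coat patching, so the discriminative signal
is a mid-scale texture that global pooling tends to wash out.

The GPN architecture addresses this with three branches over a shared
convolutional backbone whose final stage keeps full spatial resolution
(downsampling stride forced to 1). The Global and Middle branches capture
whole-face appearance at two semantic depths; the Part branch forces the
network to encode local evidence, either as six uniform horizontal stripes
(GPN) or as four learned attention regions (GPN-ST). Every branch uses the
*sum* of average- and max-pooled vectors: average pooling preserves
aggregate contrast while max pooling keeps the strongest local activation,
and their sum loses less information than either alone.

Each pooled vector passes a three-layer head — linear reduction to a common
width, batch normalization, linear classifier. Two details matter:

* the triplet losses act on the *pooled* vectors (before the head), where
  Euclidean geometry is not yet distorted by the classifier;
* the test-time feature is the *post-batch-norm* vector, whose normalized
  scale makes cosine similarity meaningful across heads.

The test embedding concatenates all head features in a fixed, serialized
order (`embedding_layout()`): 8 × 512 = 4096-d for GPN, 6 × 512 = 3072-d
for GPN-ST with the reference backbone.

## Objectives

For a batch of P identities × K images (P = 8, K = 4 by default — the
smallest shape that guarantees hard positives and negatives for every
anchor):

* **Triplet loss** (`triplet_loss`): squared-Euclidean hinge
  `[D(a,p)² − D(a,n)² + margin]₊` with batch-hard mining (farthest
  positive, nearest negative per anchor). The margin defaults to 0.3 and
  the mining strategy is configurable (`all_valid` averages over every
  triplet and is easier to reason about in tests). Distances are computed
  on un-normalized features.
* **Label-smoothed cross-entropy** (`label_smooth_ce`): the one-hot target
  is replaced by `q_y = 1 − (N−1)ε/N`, `q_other = ε/N` with ε = 0.1,
  discouraging over-confident logits on a fine-grained identity task.
* **Joint losses**: GPN averages its six triplet terms and eight
  classification terms separately (`L_T/6 + L_ID/8`); GPN-ST drops the
  triplet terms of the attention branch (`L_TL/4 + L_CL/6 + L_STN`) since
  its regions are not spatially comparable across images in the way global
  pooling is.

### Affine constraints of the attention branch

Each spatial transformer is restricted to scale + translation,
`[[sx,0,tx],[0,sy,ty]]` in normalized [−1, 1] coordinates, so a region is
an axis-aligned crop that cannot rotate or mirror. The four soft penalties
(`constraint_losses`) keep the parameters useful: scales within ±α = 0.5,
strictly positive above β = 0.1 (a negative scale would mirror the patch),
centers within ±γ = 0.71 (the stored default; the exact `sqrt(2)/2` can be
passed explicitly), and pairwise squared center distances above
δ = 0.4 with weights λ₁ = λ₂ = 0.1. Constraints act only as losses — the
parameters are never clamped — and each is zero exactly on its feasible
set, which the tests verify against a brute-force evaluator on a grid.

Design choices where the architecture was genuinely open:

* **Localization network**: per module, 1×1 convolution → global average
  pool → two linear layers, with the final layer zero-weighted and its bias
  set to a module-specific quadruple (scale 0.3, centers (±0.3, ±0.3)).
  This warm start makes the modules begin at four distinct, nearly feasible
  regions regardless of the input. Note that the warm-start centers sit
  0.36 < δ apart on adjacent pairs, so the exclusion term starts mildly
  active (L_TE = 0.16) and immediately pushes the regions apart — a
  deliberate property of the initialization, not a defect.
* **Sampling**: bilinear interpolation with zero padding and align-corners
  coordinates, the universal transformer convention; the output grid is
  6×6 by default and configurable.
* **Batch reduction**: constraint losses are computed per image (module
  pairs within one image only) and averaged over the batch.
* The transformers read the stage-4 feature map, not the raw image.

## Data pipeline

`load_dataset()` enforces the open-set invariants on any input (train and
test identity sets disjoint; every query identity has gallery images).
`pk_batches()` draws P distinct identities per batch and K images each,
with replacement only when an identity has fewer than K images.
`augment_image()` resizes to 384×192 (height × width — cattle faces are
taller than wide; 96×48 for the compact preset), flips horizontally with
probability 0.5 and applies random erasing (2–40 % of the area, aspect in
[0.3, 3.3], per-pixel uniform noise) — parameters follow the technique's
common convention and are configuration-exposed. Images are normalized to
mean 0.5 / sd 0.5 per channel; when pretrained backbone statistics existed
they would replace these, but pretrained weights are not bundled.
Gallery subsets ("Gallery n") are seeded random samples per identity; the
seed is recorded in every evaluation report since nothing in the protocol
pins which n images would be kept.

## The synthetic fixture

The reference dataset (130 000 images, 3 000 animals) is not publicly
deposited, so the package generates a synthetic stand-in that preserves the
*statistical structure* the models exploit: identities share a face-shaped
canvas with eyes, ears and muzzle (high inter-identity similarity), while a
two-tone Voronoi patch pattern (12 cells by default) carries the identity
signal, mimicking Holstein black/white patching. Per-image nuisances cover
the capture conditions the task cares about: viewpoint (horizontal shear
±0.25 for left/right views), illumination (brightness × [0.6, 1.4]),
Gaussian blur (σ ∈ [0, 1.5] px), partial occlusion (probability 0.2, area
≤ 30 % so the identity signal always survives) and sensor noise. All draws
derive from one master seed, so datasets are bitwise reproducible.

What the fixture does *not* model: photorealistic texture, pose in depth,
background clutter, growth over time, or inter-identity correlation of coat
patterns. Passing the learning tests therefore shows that the models,
losses, sampler and evaluator interact correctly and that the architecture
can exploit a coat-pattern-like signal under nuisance variation — it does
not certify accuracy on real imagery.

A deliberately weak reference point, `nearest_centroid_baseline()`
(per-identity centroids of 16×8 grayscale rasters), verifies that the
fixture is learnable at all and gives the floor the trained embeddings must
beat.

## Optimization and problem sizes

The reference schedule is SGD (momentum 0.9, weight decay 5e-4), lr 0.02
divided by 10 at epochs 90 and 120, batch 32 (8×4), test batch 8. The total
epoch count is not pinned by the schedule itself; the `reference` preset runs
140 epochs (past the last decay). The `desk` preset — used throughout the
tests and the acceptance script — scales the experiment to one CPU: tiny
backbone (four conv stages, 48/96-channel contract maps, 64-d head
features), 96×48 images, 20 training identities × 50 images, 10 unseen test
identities (10 query + 20 gallery each), 8 epochs. These sizes were chosen
once as the smallest study at which open-set transfer is meaningfully
exercised (the embedding must generalize to identities it never saw), and
they are reported by the acceptance script alongside its results. Under
this preset both variants reach Rank-1 = 1.0 on the full synthetic gallery,
above the raw-pixel baseline (~0.85) and chance (0.1), and the attention
variant leads at Gallery-1.

## Numerical choices

* The engine records a dynamic tape and walks it backward in creation
  order; all primitive gradients are hand-derived and tested against
  central finite differences (tolerance 1e-5 on random entries).
* Bilinear sampling gradients are exact except on the measure-zero lattice
  where interpolation is only one-sided differentiable; tests use generic
  (random) parameters.
* Batch norm uses ε = 1e-5 and momentum 0.1 running statistics; embedding
  extraction always runs in evaluation mode.
* Max pooling and batch-hard mining break ties by first occurrence;
  ranking ties are broken by stable gallery index order — deterministic
  and documented, since the protocol does not specify tie handling.
* Stripe boundaries are `round(seq(0, H, length.out = 7))`: the stripes
  tile the map exactly (no gap, no overlap), verified by the area-weighted
  pooling identity in the tests.
* The uniform-stripe partition runs along image height (the part-based
  convention for upright subjects); orientation is a configuration switch.
* The 12 288-d part vectors enter the triplet loss as single vectors (two
  terms, `P_Avg` and `P_Max`), not per stripe — this matches the six-term
  census of the joint loss.

## Limitations

* The reference backbone is randomly initialized; ImageNet-pretrained
  weights are an optional input the package will not fetch, and the
  headline accuracies of the original large-scale study are out of reach
  without its dataset and GPU-scale training. The desk-scale study verifies
  mechanism, not field accuracy.
* Single device only; no mixed precision, no re-ranking, no cross-camera
  protocol (the data model has no camera metadata).
* The face detection/cropping stage that precedes re-identification in a
  deployed system is out of scope: the package consumes already-cropped
  face images.
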