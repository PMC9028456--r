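# cowreid

Open-set re-identification of individual Holstein cattle from face images.

Identifying a cow that was never seen during training is a retrieval
problem, not a classification problem: given a *query* face image, rank a
*gallery* of reference images so that images of the same animal come first.
`cowreid` implements a multi-branch deep embedding model for this task — the
Global-and-Part Network (GPN) and its spatial-transformer extension
(GPN-ST) — together with the full training objective, the identity-balanced
sampling and augmentation pipeline, the ranking evaluation protocol, and a
deterministic synthetic fixture generator, all exercisable end-to-end on a
CPU. The package is aimed at researchers in animal biometrics and precision
livestock farming who need a tested, self-contained reference
implementation of this model family.

Because no deep-learning framework is assumed, the package carries its own
network engine: reverse-mode automatic differentiation over R arrays with
compiled (Rcpp/RcppArmadillo) kernels for convolution, pooling and bilinear
affine sampling. Every analytic gradient is tested against finite
differences.

## The model

A convolutional backbone (reference: ResNet50 with the stage-4 downsampling
stride set to 1, so the final feature map keeps the stage-3 resolution)
yields two maps per image: a mid-level map (1024 channels) and a high-level
map (2048 channels). Three branches pool them:

* **Global branch** — GAP and GMP over the high-level map give
  `G_Avg, G_Max ∈ R^2048`; `G = G_Avg + G_Max` feeds a classifier head.
* **Middle branch** — the same dual pooling on the mid-level map gives
  `M ∈ R^1024`.
* **Part branch (GPN)** — the high-level map is partitioned into 6 uniform
  horizontal stripes; per-stripe dual pooling gives flattened
  `P_Avg, P_Max ∈ R^12288`, summed into `P`, whose six 2048-d stripe
  vectors feed six heads.
* **Part branch (GPN-ST)** — four spatial-transformer modules each predict
  a scale+shift affine `[[sx,0,tx],[0,sy,ty]]`, bilinearly sample a region
  from the high-level map, and feed a head. Soft constraint losses keep the
  regions bounded (`L_SS`), positive (`L_SP`), on-canvas (`L_TS`) and
  mutually separated (`L_TE`):
  `L_STN = L_SS + λ₁ L_SP + L_TS + λ₂ L_TE`
  with α = 0.5, β = 0.1, γ = 0.71, δ = 0.4, λ₁ = λ₂ = 0.1.

Each head is linear(→512) → batch-norm → linear(→classes); the post-BN
vector is the test-time feature. Embeddings concatenate the head features:
8 × 512 = **4096-d** for GPN, 6 × 512 = **3072-d** for GPN-ST, compared by
cosine similarity.

Training minimizes, for GPN,
`L = L_T/6 + L_ID/8` (six batch-hard triplet losses on the pooled vectors,
eight label-smoothed cross-entropies), and for GPN-ST
`L = L_TL/4 + L_CL/6 + L_STN` (no triplet terms in the attention branch).
Batches are P=8 identities × K=4 images; SGD with momentum 0.9, weight
decay 5e-4, lr 0.02 divided by 10 at epochs 90 and 120.

Evaluation reports CMC Rank-1/5/10 and mAP
(`AP = (1/N) Σᵢ i/pᵢ` over the ranks `pᵢ` of the correct matches) against
gallery subsets capped at 1, 2, 3, 4, 5, 10, 15 and 20 images per identity.

## Worked example

Generate a synthetic open-set dataset (20 training identities, 10 unseen
test identities with 10 query + 20 gallery images each), train the compact
CPU variant of each model, and evaluate:

```r
library(cowreid)

ds <- generate_dataset("synth", num_train_ids = 20, num_test_ids = 10,
                       imgs_per_train_id = 50, query_per_id = 10,
                       gallery_per_id = 20, image_size = c(96, 48),
                       global_seed = 7)
print(ds)
#> <reid_dataset> 1300 images: gallery=200, query=100, train=1000
#>   20 train identities, 10 test identities (open set)

nearest_centroid_baseline(ds)$rank1   # raw 16x8-pixel baseline
#> [1] 0.85

fit <- train_model(ds, train_config("desk", "gpn", epochs = 8, seed = 1),
                   verbose = TRUE)
#> [gpn/desk] epoch 0  lr 0.02  loss 13.6809
#> ...
#> [gpn/desk] epoch 7  lr 0.02  loss 2.3259

evaluate_model(fit$model, ds, gallery_caps = c(1, 20), seed = 1)
#>   cap rank1 rank5 rank10       map
#> 1   1  0.89     1      1 0.9416667
#> 2  20  1.00     1      1 0.8857911
```

The trained 512-d embedding (tiny backbone: 8 heads × 64) ranks every query
correctly against the full gallery (Rank-1 = 1.00) and beats the raw-pixel
baseline (0.85) and chance (0.10); the GPN-ST variant reaches 0.94 at
Gallery-1 versus 0.89 for GPN under the same budget, consistent with the
intended benefit of the attention Part branch. Training each variant takes
about a minute on one CPU.

The same pipeline is scriptable from a shell:

```sh
inst/cli/cowreid synth-data --out synth --seed 7
inst/cli/cowreid train --data synth --config desk.yaml --out run
inst/cli/cowreid evaluate --checkpoint run/checkpoint.rds --data synth
inst/cli/cowreid visualize-parts --checkpoint run/checkpoint.rds \
    --image synth/query/0020/001.png --out parts
```

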