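# slicfuse

Building blocks for two-class histopathology image classification, written
for method developers who want every stage of a superpixel-guided deep-feature
pipeline to be testable without a dataset download: entropy-guided SLIC
superpixel segmentation, deep-weighted averaging feature fusion (DWAFF) of
multi-backbone feature matrices, metaheuristic wrapper feature selection
(particle swarm and red deer optimization), formula-level classifiers, and a
stratified K-fold evaluation harness with the full confusion-matrix metric
suite. Synthetic generators produce histology-like nucleus images with
pixel-level ground truth and class-structured feature triplets, so the whole
stack runs end to end on a laptop.

## The method

**Segmentation.** A grayscale image with histogram probabilities
`p_0, ..., p_255` is first cut at thresholds `t_1 < ... < t_k` chosen by the
Kapur maximum-entropy rule

```
(t_1, ..., t_k) = argmax  Σ_seg [ log P_seg − Σ_{i∈seg} p_i log p_i / P_seg ],
```

exact (exhaustive) for k ≤ 2 and by monotone coordinate ascent for k ≥ 3.
Each intensity interval is then remapped by a two-piece power curve
`f(x) = a x^r + b` (convex below the interval's probability-weighted turning
point, concave above it), equalizing contrast before clustering. The modified
SLIC stage clusters pixels in the three-dimensional `(x, y, gs)` space with
the distance `d'^2 = d_spatial^2 + α · d_gray^2` (default `α = (S/m)^2`, seed
spacing `S = sqrt(N/M)`, compactness `m ∈ [1, 40]`), using circular search
windows of radius `S`, Lloyd-style center updates, and adjacency-based
merging of undersized superpixels. Dark (nuclei-dense) superpixels below the
global Otsu threshold form the region of interest.

**Fusion.** Three backbone feature matrices (deepest first) are combined as
`w1·f152 + w2·f101 + w3·f50` with simplex weights found by grid search
against a cross-validated KNN reference score; the faithful training-time
variant divides by 3 and adds per-class mean offsets, while the leak-free
variant is a plain convex combination usable on unlabeled data.

**Selection.** Particle swarm optimization (linearly decaying inertia
0.9 → 0.45) and red deer optimization (roaring, commander–stag fights,
fitness-proportional harems, midpoint-plus-noise offspring) search a
sigmoid-logit encoding of feature masks; a candidate's fitness is its
stratified 3-fold KNN accuracy minus a sparsity penalty.

**Classification and evaluation.** Softmax discriminant (log-sum-exp of
`−λ‖v − v_n‖²`), Bayesian linear discriminant (ridge-regularized Bayesian
regression to class targets 0.15/0.85 with Gaussian predictive mean and
variance), a single-hidden-layer sigmoid MLP trained on the squared-error
cost, and delegated SVM-RBF / decision-tree / random-forest / weighted-KNN
baselines all share one fit/predict contract. Stratified K-fold
cross-validation (K ∈ {2, 4, 5, 8, 10}) scores everything with accuracy,
error rate, F1, MCC, Jaccard, G-mean and Cohen's kappa, with the clinical
convention that *benign* is the positive class.

## Worked example

```r
library(slicfuse)

im  <- make_image(synth_image_spec(class = "aca", seed = 42))
seg <- slic_segment(im$image, slic_config(M = 48, k_thresholds = 1))
seg
#> SLIC segmentation: 64 x 64 image, 53 superpixels
#>   thresholds: 153
#>   iterations: 4 (converged)
boundary_recall(seg$labels, im$mask)
#> [1] 1
```

The segmenter found one maximum-entropy threshold (intensity 153, between
the dark nuclei and the bright stained background), converged in 4
iterations, and produced 53 superpixels after merging; every ground-truth
nucleus boundary pixel lies within 2 px of a superpixel boundary (boundary
recall 1.0).

```r
res <- run_experiment(run_config(scenario = "seg", n_per_class = 12, K = 5, seed = 1))
res
#> Scenario: seg
#>   K5: accuracy 88.33% (sd 16.24)
#>   mean accuracy across K: 88.33%
```

This runs the full pipeline — 24 synthetic images, segmentation-guided ROI
features at three scales, DWAFF fusion at the 0.45/0.35/0.20 operating
point, and a weighted-KNN classifier under stratified 5-fold
cross-validation — and reports the per-K fold-averaged accuracy.

```r
metrics(confusion(c(0,0,0,0,1,1,1,1), c(0,0,1,0,1,1,0,1)))
#> accuracy 75.00%  error 25.00%  F1 75.00%  Jaccard 60.00%  G-mean 75.00%
#> MCC 0.5000  kappa 0.5000
```

A command-line front end over the same functions lives at
`inst/cli/slicfuse.R` (subcommands `simulate`, `segment`, `run`).

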