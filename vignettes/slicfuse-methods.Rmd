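---
title: "Methods: superpixel-guided fusion, selection and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: superpixel-guided fusion, selection and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicfuse)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the synthetic study conditions, and
the numerical and design choices made where the underlying method
description left them open.

## 1. Preprocessing and the adaptive fuzzy filter

Images are converted to grayscale with BT.601 luma weights
(0.299, 0.587, 0.114) and resized with bilinear interpolation under
pixel-center alignment, so the identity resize is exact and constants are
preserved. The denoising filter is a Gaussian-membership fuzzy-weighted
mean: within a `window × window` neighborhood (default 3, odd), a neighbor
with intensity $I_n$ contributes with weight
$\mu = \exp(-(I_n - I_c)^2 / 2\sigma^2)$ relative to the window center
$I_c$ (default $\sigma = 30$ intensity levels). Similar pixels are averaged,
dissimilar ones are discounted, so noise inside homogeneous tissue is
suppressed while nucleus edges survive. The exact filter behind the
published pipeline is not specified anywhere; this membership-weighted mean
is the package's own, documented stand-in — the simplest construction that
is both "fuzzy" (graded membership) and "adaptive" (weights depend on the
local contrast). All borders reflect, which avoids dark halos at image
edges.

## 2. Entropy-guided contrast enhancement

The 256-bin intensity histogram is cut at $k$ thresholds (default 2,
supported 1–4) maximizing the Kapur criterion: the sum over segments of the
Shannon entropy of the conditional within-segment distribution,
$\sum_\text{seg} [\log P_\text{seg} - \sum_{i} p_i \log p_i / P_\text{seg}]$.
For $k \le 2$ the search is exhaustive, hence exact; for $k \ge 3$ it is
coordinate ascent from quantile starts — each sweep re-optimizes one
threshold with the others fixed, so the criterion never decreases, and the
sweep stops when no move helps. Threshold ties break to the
lexicographically smallest tuple, making results reproducible.

Each source interval $[X_i, X_{i+1}]$ (intensities clamped to $\ge 1$, the
power-curve domain) maps onto equal-width targets partitioning $[1, 255]$
through $f(x) = a x^r + b$ fitted through the interval endpoints. The curve
is convex from $X_i$ up to the interval's probability-weighted centroid
$X_m$ and concave (the reflected curve) beyond it, with $f(X_m)$ pinned to
the target midpoint. The exponent is one global $r$ (default 2,
configurable); per-interval exponents would add parameters without a
criterion to set them. Degenerate situations fall back gracefully: $r = 1$
uses a single straight line (the two-piece split is vacuous for an affine
map), a turning point within half an intensity level of an endpoint uses a
single curve, an empty interval maps to its target midpoint, and intensity
0 inherits the mapping of 1. The composed transform is monotone
non-decreasing by construction, which the tests assert.

## 3. Modified SLIC clustering

Clustering runs on the 3-vector (x, y, grayscale). With $N$ pixels and $M$
requested superpixels, seeds sit on a grid with spacing $S = \sqrt{N/M}$ —
the only spacing consistent with each superpixel holding $N/M$ pixels on a
2-D grid — then move to the minimum-gradient position in their 3×3
neighborhood (squared central differences; ties keep the grid position).
The distance is $d'^2 = d_{ss}^2 + \alpha\, d_{gs}^2$ with
$\alpha = (S/m)^2$ by default, which makes a grayscale difference of $m$
"cost" as much as a spatial offset of $S$; this is the standard SLIC
normalization expressed in the modified algorithm's notation, and $\alpha$
can be overridden directly. Compactness $m$ defaults to 20 (range 1–40;
larger favors round, regular superpixels).

Each center claims pixels within a circular window of radius $S$; a pixel
takes the center minimizing $d'$, ties to the lower label, and a pixel's
current center always remains a candidate. That last rule, plus mean
updates of (x, y, gs), makes the summed squared distance a Lloyd-type
descent objective: assignment cannot increase any pixel's term and the mean
minimizes the squared cost given assignments, so the recorded cost trace is
non-increasing — asserted per iteration in the tests. Iteration stops when
the mean center displacement drops below 0.5 px or after 10 iterations
(standard SLIC practice; segmentations in this package converge in 3–5).
Pixels missed by every window (possible at image corners) are assigned to
the nearest center by $d'$.

Post-processing relabels connected components (4-connectivity) smaller than
`min_size_frac · S²` pixels (default fraction 0.25) into the adjacent
segment sharing the longest boundary, ties to the smaller label, smallest
offender first; final labels are compacted to $0..n-1$ in scan order. The
region of interest keeps superpixels whose mean enhanced intensity falls
below the global Otsu threshold — nuclei-dense tissue is dark — which is
again a documented stand-in: how the published pipeline derives its final
ROI from superpixels is never stated.

## 4. DWAFF fusion

Fusion weights live on the probability simplex with $w_1$ on the deepest
backbone. *Faithful* mode reproduces the published arithmetic exactly: the
weighted sum is divided by 3 (the divisor printed in the per-class fusion
equations, though absent from the generic weighted-sum equation; a
`divide_by_three` switch exposes the other reading) and the class mean —
the average over backbones of the grand mean of that class's entries — is
added per row. Because the offset uses labels, faithful mode is only valid
on training data; inside cross-validation the offsets are estimated on
training folds. *Leak-free* mode (the pipeline default) is the plain convex
combination, bounded by the input range and usable at inference. The class
mean is a scalar per class, not a per-feature vector — the narrower reading
of "average of mean values", and the only one that yields a single number
to add.

The weight search enumerates the simplex grid at step 0.05 — the published
operating point (0.45, 0.35, 0.20) does not exist on the coarser 0.1 grid
that the method text also mentions — and scores each triple by mean
stratified K-fold accuracy of an unweighted KNN (k = 5) on the fused
features, averaged over the requested K values, with folds fixed once so
every triple faces the same splits. Ties break toward larger $w_1$, then
$w_2$, reflecting the deeper-backbone-first ranking. KNN is used as the
reference classifier because the search needs something cheap and
deterministic; the published procedure says only "train the classifiers".

## 5. Metaheuristic feature selection

Positions encode masks through a sigmoid: feature $i$ is kept iff
$p_i > 0$, with an argmax rescue so masks are never empty. The wrapper
fitness is the mean stratified 3-fold accuracy of KNN (k = 5) on the masked
features minus $\lambda_s \cdot n_\text{selected}/d$ with
$\lambda_s = 0.01$.

**PSO.** Velocities follow
$q \leftarrow w q + c_1 r_1 (p_\text{best} - p) + c_2 r_2 (g_\text{best} - p)$
with inertia decaying linearly $0.9 \to 0.45$ — the printed decay formula is
ambiguous about operator precedence, and the linear reading is the only one
consistent with both stated endpoints. The published configuration fixes
$r_1 = r_2 = 0.85$; that faithful mode is the default, with per-step
uniform draws available as `r_mode = "random"`. Velocities are clamped per
coordinate and positions clipped to the box.

**RDO.** The population ranks into males (top 12 of 100 by default) and
hinds; a $\gamma = 0.6$ share of males are commanders. The printed male,
hind and population counts are mutually inconsistent (12 + 58 ≠ 100); the
package conserves the population by setting hinds = population − males,
with an `n_hinds` override for the legacy value. Roaring perturbs a male by
$\pm a_1((UL-LL)a_2 + LL)$ with greedy acceptance; fights evaluate the two
midpoint-plus-noise candidates against commander and stag and keep the best;
harems are fitness-proportional with a largest-remainder correction so hind
counts sum exactly; offspring sit at the parent midpoint plus $(UL-LL)c$.
The event probabilities (roar 0.23, fight 0.47, mating 0.78) gate each
event as a Bernoulli draw — the published table lists them without wiring,
and this is their standard role. The stochastic factors $a, b, c$ are drawn
per coordinate: with a single scalar draw the moves would be rank-one
(identical shift on every coordinate) and the algorithm could never refine
coordinates independently.

Two wrapper-level choices deserve emphasis. First, the selection search box
is the narrow logit interval $[-0.5, 0.5]$: positions start near the
keep/drop boundary so single-feature flips stay within one velocity step,
which matters in a 100-dimensional mask space; the wrapper's PSO default
also switches to per-step random factors, which explore that space better
than the fixed published factor. Second, the wrapper fitness itself caps
exact recovery: on 60 samples, 3-fold KNN accuracy rewards some noise
features (classic selection overfitting), so masks mixing most — not all —
planted features with a few noise features can outscore the exact planted
mask. The recovery the tests assert (median ≥ 8 of 10 planted features over
five seeds) is what the fitness optimum actually supports under these
conditions, not an optimizer shortfall.

The sphere benchmark used to validate both optimizers is defined on the
unit box $[-1, 1]^d$, matching the scale of the logit boxes the optimizers
search in this package; rastrigin keeps its canonical
$[-5.12, 5.12]^d$ domain. RDO needs a few hundred generations to push the
sphere value below $10^{-2}$ at dimension 5 — its refinement mechanism is
greedy random perturbation, which converges slowly near an optimum — so the
benchmark tests give it a 300-generation budget; PSO reaches machine-level
precision in 200 iterations.

**Entropy diagnostics.** Approximate entropy uses template length $n = 2$
and tolerance $0.2 \times$ series SD with self-matches included (so
constant series give exactly 0); Shannon entropy uses natural logarithms
with $0 \log 0 = 0$ and a 32-bin equal-width histogram for raw-value input;
fuzzy entropy uses mean-subtracted templates, Chebyshev distances,
membership width 0.25, $M - n$ templates and excludes self-pairs. These
parameter values are the package's choices — the defining formulas carry no
parameters at all.

## 6. Classifiers

**SDC** scores class $j$ by $\log \sum_n \exp(-\lambda \lVert v - v_n^j
\rVert^2)$ (computed with a stable log-sum-exp; $\lambda = 0.458$ by
default, the published value) and breaks ties to the benign class. Large
$\lambda$ recovers 1-NN; small $\lambda$ on balanced classes approaches a
nearest-centroid rule — both asserted against oracles.

**BLDC** is Bayesian linear regression of class targets on bias-augmented
features: posterior precision $\beta V V^\top + \mathrm{diag}(\alpha, ...,
\alpha, \varepsilon)$, solved with `solve()` rather than an explicit
inverse; predictive mean $v^\top U$ and variance $1/\beta + v^\top H v$,
which strictly exceeds the noise floor $1/\beta$ for any input since $H$ is
positive definite. Targets default to (0.15, 0.85) — the published "average
target values for each class", which only makes sense for a
regression-to-targets classifier — with the decision threshold at their
midpoint and midpoint ties resolved to the benign class. $\alpha$ and
$\beta$ are fixed configuration values (both default 1): no evidence-update
rule is given for them, and inventing an EM loop would add behavior with no
published surface to test against. With $\alpha = \varepsilon = 0$ the fit
reduces to ordinary least squares, the basis of the package's exactness
test.

**MLP** is one sigmoid hidden layer (default 20 units) and a sigmoid
output trained by (mini-)batch gradient descent on the squared-error cost,
inputs standardized with training statistics, learning rate 0.45 (the
published value) and an epoch cap of 15 (the published training budget) —
both configurable, and tasks like XOR that need far more than 15 epochs
raise the cap explicitly. The published training method is
Levenberg–Marquardt; plain gradient descent on the same cost is implemented
instead, since the cost function, not the second-order optimizer, is what
downstream behavior depends on.

**Baselines** delegate: SVM-RBF to `e1071::svm` with the published kernel
width $\sigma = 98$ mapped to $\gamma = 1/(2\sigma^2)$ and the "support
vector coefficient" 1.8 mapped to the cost parameter (the published SVM
parameters do not correspond one-to-one to standard hyperparameters; this
mapping is a documented interpretation), decision tree to `rpart` with
entropy splits and depth 14, random forest to `ranger` with 150 trees and
depth 15, and KNN to an in-package weighted variant (k = 5, Euclidean,
inverse-distance weights) because no installed package provides distance
weighting. KNN-style classifiers standardize features with training
statistics before computing distances; without this, raw feature scale
accidents — not information — decide neighborhoods.

## 7. Evaluation

Folds are stratified: within each class, a seeded shuffle deals samples
round-robin into K folds, so fold sizes differ by at most one per class and
K = 2 remains balanced. Benign is the positive class (TP = benign called
benign), per the clinical framing. All seven metrics come from the
confusion matrix exactly as defined — accuracy, error rate,
F1 = 2TP/(2TP+FP+FN), MCC (computed with a product-of-square-roots
denominator to avoid integer overflow), Jaccard, G-mean, and kappa with
chance agreement from the marginal products. A metric whose denominator
vanishes is reported as 0 and listed in a `flagged` field — explicit,
testable degenerate behavior. `cross_validate()` takes a pipeline factory
`function(features, labels)` returning a predictor, so *everything* fitted
— fusion offsets, selection masks, classifier weights — is fitted inside
the training folds; a canary test plants a perfect predictor in held-out
rows only and asserts accuracy stays at chance.

## 8. Synthetic study conditions

The image generator emulates H&E-like tissue at the level this pipeline
consumes: a bright stained background (mean 180) with per-image brightness
jitter (SD 12, eosin variability), per-image nucleus intensity jitter
(mean 90, SD 20, hematoxylin variability), hard-edged mid-intensity
stromal clutter disks (4–10 per image, ~150), dark elliptical nuclei with
sinusoidally perturbed boundaries, and Gaussian pixel noise (SD 18), on
64×64 grids. Benign images carry 8 nuclei with low boundary irregularity
(0.12); abnormal images carry 10 with high irregularity (0.55) — mild
hypercellularity plus strongly irregular nuclear shape, the morphological
signature the pipeline is supposed to exploit. The per-image stain jitter
is the deliberate difficulty: fixed-threshold global statistics (histogram
bins, dark-pixel fractions) degrade under it, while the segmentation path —
per-image maximum-entropy thresholds, Otsu-selected dark superpixels,
statistics on the ROI-extracted image — adapts. This is what gives the
scenario comparison (none / segmentation / segmentation + selection) its
direction on synthetic data, for the same reason adaptive segmentation
helps on real slides.

The feature generator produces three correlated backbone matrices:
lognormal noise (positively skewed, like ReLU activations; target skewness
4) correlated across backbones on the log scale (default 0.8), with the
first `n_informative` columns shifted additively by 1.0 in the abnormal
class, identically in all backbones, and values clipped at 0.

What passing these tests does **not** show: the generators contain no
color, no stain physics, no tissue architecture, no label noise, and their
class signal is planted rather than emergent — results on them validate the
machinery (contracts, arithmetic, leakage containment, directional
behavior), not clinical performance. Published headline accuracies depend
on a real 10,000-image dataset and pretrained convolutional backbones,
both outside this package's scope; the feature-extractor adapter
(`extract_features`) is the hook for plugging real backbones in.

The reference problem sizes used throughout the test suite — 64×64 images,
20 images per class and 5 replicate seeds for the scenario comparison, 60
samples × 100 features for selection, 100 random 16-level histograms for
the thresholding oracle — are the package's chosen study conditions: small
enough to run anywhere, large enough that every directional claim the tests
make is driven by the planted structure rather than sampling luck.

## 9. Known limitations

* The adaptive fuzzy filter and the superpixel-to-ROI rule are documented
  stand-ins; the source method names both stages but specifies neither.
* The RDO mating/roaring equations are implemented as printed; their
  upward-biased offspring shift and non-adaptive step scale make RDO a slow
  refiner near optima (hence its larger benchmark budget).
* Faithful DWAFF fusion uses labels at feature-construction time by
  definition; the package contains the leakage (train-fold offsets inside
  CV, leak-free default elsewhere) but cannot remove it from the faithful
  arithmetic itself.
* Wrapper selection with a 3-fold KNN fitness overfits small samples; see
  Section 5 for why recovery saturates below 10/10.
* `max_entropy_thresholds` for k ≥ 3 is a local ascent; only k ≤ 2 carries
  an exactness guarantee (and the pipeline default uses k ≤ 2).
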