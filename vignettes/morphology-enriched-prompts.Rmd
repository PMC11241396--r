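---
title: "Morphology-enriched prompt building: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-enriched prompt building: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoprompt)
```

## The method

Histopathology patch collections are usually annotated with a single binary
label (healthy vs cancer) per patch, which is far too coarse to caption the
morphological diversity a generative model should learn. Morphology-enriched
prompt building (MEP) manufactures richer captions in three unsupervised
steps:

1. embed every patch with a fixed feature extractor,
2. cluster the embeddings with k-means, choosing the number of clusters by
   minimizing the SD validity index over a scanned range, and
3. fill the template
   `"Histology image of LABEL tissue, morphology type INDEX"`
   with the patch's label word and its cluster index.

The cluster index acts as a pseudo-annotation: patches that share staining
profile, cellular density or tissue architecture land in the same cluster
and therefore share a caption token, so a text-to-image model conditioned on
these captions can be steered toward specific morphology modes. The baseline
it is compared against uses the label-only template
`"Histology image of LABEL tissue"`.

## The SD validity index

The number of morphology clusters is the method's one structural choice, and
it is made by minimizing

$$\mathrm{SD}(k) \;=\; \alpha\,\mathrm{Scat}(k) + \mathrm{Dis}(k),$$

$$\mathrm{Scat}(k) = \frac{1}{k}\sum_{i=1}^{k}
  \frac{\lVert \sigma(C_i)\rVert}{\lVert \sigma(X)\rVert},
\qquad
\mathrm{Dis}(k) = \frac{D_{\max}}{D_{\min}}
  \sum_{i=1}^{k}\Bigl(\sum_{j=1}^{k}\lVert v_i - v_j\rVert\Bigr)^{-1},$$

where $\sigma(\cdot)$ is the per-dimension **population** variance vector of
a point set, $\lVert\cdot\rVert$ the Euclidean norm, $v_i$ the cluster
centroids, and $D_{\max}$, $D_{\min}$ the largest and smallest inter-centroid
distances. Scat measures average within-cluster scattering relative to the
total scattering of the data; Dis grows when centroids crowd together. The
weight $\alpha$ is set, as is conventional for this index, to
$\mathrm{Dis}(k_{\max})$ of the largest scanned $k$, which puts the two terms
on a comparable scale; `select_k()` also accepts an explicit `alpha`.

Numerical conventions, all of which matter in edge cases:

* the index requires $k \ge 2$ (no inter-centroid distances otherwise);
* coincident centroids ($D_{\min} = 0$) make the index undefined; such a
  $k$ is recorded as `NA`, excluded from the argmin with a warning, and the
  scan errors only if *every* $k$ degenerates;
* ties in the argmin break toward the smallest $k$ (parsimony, determinism);
* single-member clusters contribute zero scattering.

## k-means

The clustering itself is plain Lloyd iteration, written in-package because
the scan needs a contract the stock implementations do not expose together:
seeded determinism, best-of-`n_restarts` selection by inertia, and explicit
empty-cluster repair (an emptied cluster is reseeded with the farthest
member of the largest cluster, so a fitted model never contains an empty
cluster). Seeding is greedy k-means++: each new center is chosen among
$2 + \lfloor\log k\rfloor$ candidates drawn proportionally to the squared
distance to the nearest existing center, keeping the candidate that most
reduces the total potential. This refinement of the ++ scheme — the default
in widely used k-means implementations — markedly reduces the chance that a
well-separated component is missed at large $k$. Defaults: 10 restarts, 100
Lloyd iterations. An independent k-means implementation is used in the test
suite to cross-check assignments and inertia on separated data.

Features are not re-standardized before clustering by default: the bundled
reference extractor already normalizes every component into $[0,1]$, and for
external extractors the choice is left to the caller (a z-scoring step can
be applied to the matrix before `select_k()` if desired).

## Prompt rendering and balancing

Cluster indices are 0-based and rendered, by default, as lower-case English
words ("morphology type five"); a numeral rendering ("morphology type 12")
is available since captions are consumed as free text and either reading is
defensible. With $k$ clusters and 2 labels the caption vocabulary has
$2k$ entries (66 at $k = 33$).

Because morphology clusters are never equally populated, the dataset handed
to a fine-tuning stack is rebalanced:

* `select_top_prompts()` keeps the `per_class` most populated captions per
  class (21 per class — 42 in total — at the protocol's reference scale),
  breaking count ties lexicographically;
* `undersample_uniform()` draws a subset of exact size `total` with
  per-caption quotas `floor(total/G)` plus one for the first `total mod G`
  groups in a fixed priority order; at the reference scale of 51,000 over
  42 groups this yields counts of 1214 or 1215, with 12 groups at 1215;
* `split_balanced()` computes validation quotas by the same rule on
  `val_size` (50,000/1,000 at reference scale, giving validation counts of
  23 or 24 with 34 groups at 24) and assigns the remainder to training.

The remainder (+1) priority order — alternate classes, lexicographic caption
order within class — is a design choice the protocol leaves open. Using the
*same* fixed order for the undersampling quotas and the validation quotas is
what guarantees the ±1 per-caption uniformity on the training side too: the
train count of group $g$ is the difference of two step functions over the
same group ordering, which can only take two adjacent values. The baseline
copy of a balanced dataset is produced by `strip_morphology()`, which
rewrites captions label-only on the identical image set, preserving
comparability of the two conditioning strategies.

## Generation metrics

`fid()` fits a mean and unbiased covariance to each embedding set and
evaluates the Fréchet (2-Wasserstein) distance between the Gaussians,

$$\lVert\mu_1-\mu_2\rVert^2 + \mathrm{Tr}\bigl(\Sigma_1 + \Sigma_2 -
  2(\Sigma_1\Sigma_2)^{1/2}\bigr),$$

computing the cross term as
$\mathrm{sqrtm}(\mathrm{sqrtm}(\Sigma_1)\,\Sigma_2\,\mathrm{sqrtm}(\Sigma_1))$
through symmetric eigendecompositions. Eigenvalues whose magnitude is below
$10^{-8}$ of the spectral radius may be clamped to zero; anything more
negative raises an error rather than being silently truncated. This route is
numerically stable for the near-singular covariances that small embedding
sets produce; the test suite checks it against an independent
eigendecomposition of the nonsymmetric product $\Sigma_1\Sigma_2$.

`improved_precision_recall()` estimates each set's manifold as the union of
balls centered at its points with radius the distance to the `k_nn`-th
nearest neighbor within the same set (self excluded). Precision is the
fraction of synthetic points falling inside the real manifold, recall the
fraction of real points inside the synthetic manifold; points exactly on a
ball boundary count as inside. `k_nn` defaults to 3, the customary choice of
the metric's reference implementation, and is exposed. All pairwise
distances are computed exactly (no approximate neighbors), which is the
right trade-off at the package's operating sizes (up to a few times
$10^4$ points).

The embedder behind these metrics is a contract: any fixed model mapping
images to vectors works, a pretrained convolutional embedder being the
conventional choice; desk-scale runs use the bundled reference extractor.

## Coverage analysis

`project_embeddings()` fits a 2-D projector **on the real embeddings only**
and transforms both sets, so the synthetic data are viewed strictly through
the structure of the real distribution — a synthetic set cannot stretch or
recenter the map. The projector is again a contract (`fit`/`transform` plus
a seed); the bundled reference projector is rank-2 PCA, and an identity
projector makes the path exactly testable on 2-D inputs. Nonlinear
neighborhood-embedding projectors plug in through the same contract, with
their hyperparameters owned by the adapter.

Where the overlap of projected clouds is usually judged by eye,
`occupancy_coverage()` adds a deliberately simple scalar: the real bounding
box is divided into a `grid_n` × `grid_n` grid (default 50) and the statistic
is the fraction of real-occupied cells also occupied by synthetic points
(synthetic points outside the box are ignored). It is monotone in the
synthetic set and bounded in $[0,1]$; it is a summary of a picture, not a
replacement for the manifold metrics above.

## The augmentation benchmark

`run_grid()` trains one classifier per (regime, ratio, fold) cell: `n_real`
real samples plus `round(n_real * ratio / 100)` synthetic samples are drawn
class-balanced (±1, the positive class taking the extra on odd counts)
without replacement from fixed pools, a classifier is trained through a
pluggable trainer contract with model selection by validation AUC, and the
test AUC is recorded. The default grid — regimes 10, 25, 50, 100, 500,
1000, 10,000; ratios 0–300%; 10 folds — enumerates 420 cells. Fold seeds
are shared across cells so that folds are comparable, trainer failures are
recorded per cell rather than aborting the grid, and `summarize_grid()`
reports median and quartiles per cell.

The reference trainer is a closed-form ridge classifier on feature vectors
with the penalty chosen on the validation set. It is the package's own
reference implementation of the classifier contract — deterministic, fast,
and sufficient to exercise every property of the harness; deep classifiers
plug in through the same contract. AUC is computed from midranks (ties count
one half) and is checked against an exhaustive pair-counting oracle in the
tests. The benchmark reports against an explicit held-out test pool supplied
by the caller.

## Synthetic fixtures: what they emulate and what they do not

`make_patch_dataset()` produces stain-like RGB patches from procedural
morphology recipes: a base hue from a 12-entry stain-inspired palette,
nucleus-like blobs with recipe-specific density and radius, and Gaussian
texture grain. Recipes are constructed to be separable in any reasonable
color/texture feature space (palette entries sit at least two histogram bins
apart in one channel), so clustering at the true number of recipes recovers
the latent partition — the property the pipeline's tests rely on. Labels are
drawn as a seeded random subset of size `round(n * cancer_fraction)`,
mirroring the loose patch-level annotation of real benchmarks where label
and morphology are correlated but not identical. These fixtures emulate the
*structure* of a patch dataset (ids, pixels, labels, latent morphology), not
histology itself: no stain physics, no cell segmentation realism, no
spatial correlation across patches. Tests passing on them demonstrate the
pipeline's mechanics and arithmetic, not performance on real tissue.

`make_feature_mixture()` generates isotropic Gaussian mixtures with centers
at mutual distance at least `separation` × `within_sd` (placement is
rejection-sampled with a bounded retry budget; the center cloud scale is
chosen so the constraint almost always holds at the first draw). It stands
in for a deep-feature space with known cluster structure. The reference
recovery condition used throughout — 33 components in 32 dimensions, 100
points per component, separation 8 — was chosen to match the protocol's
selected cluster count at a size a single CPU scans in about a minute;
separation 8 is "well separated but not trivial" in the sense that raw
within-cluster point distances ($\approx\sigma\sqrt{2d} = 8$) are of the
same order as the minimum center separation.

`make_benchmark_pools()` draws labeled feature pools for the benchmark from
two Gaussian class distributions whose means differ by `class_sep` (default
1.5, giving a Bayes AUC around 0.86 — a deliberately non-trivial task at
small n). The synthetic pool's means are shrunk by 10% and its spread
inflated by 5%, emulating a generative model that approximates but does not
equal the real distribution, so augmentation helps in low-data regimes and
plateaus in large ones.

## Determinism

Every stochastic operation takes an integer seed and restores the caller's
RNG state; sub-streams (restarts, folds, per-group draws) derive their seeds
from the master seed through a fixed linear-congruential map, so results are
bit-reproducible for identical inputs and seeds. Ordering is lexicographic
by id in the C locale everywhere, making outputs independent of filesystem
enumeration and locale settings.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
the cluster-count recovery scan uses the 3300 × 32 mixture above; metric
oracles run on instances up to 200 points per set; the balancing arithmetic
is exercised at its full reference scale (51,000 ids over 42 caption
groups); and the benchmark grid runs all 420 cells on pools of 21,000 real
and 62,000 synthetic feature vectors with the ridge trainer. These sizes
were chosen as the smallest at which every structural number of the
protocol is reproduced exactly.

## Known limitations

* The foreground filter (minimum-channel whiteness threshold 220/255, at
  least 10% tissue pixels) is a simple documented rule; real slide QC
  pipelines use more elaborate criteria. Both parameters are exposed.
* The reference extractor is a global color/texture descriptor: adequate to
  separate procedural recipes and to exercise every contract, but far below
  a pretrained deep extractor on real tissue. MEP's cluster quality on real
  data is bounded by the extractor plugged in.
* The SD index compares k-means solutions of different k on equal terms
  only when the fits are near-optimal; the greedy seeding and restarts make
  this reliable at the scanned sizes, but very large k on very small n can
  still degenerate (and is reported as such rather than silently chosen).
* `occupancy_coverage()` depends on the grid resolution and on the real
  bounding box; it is intended for comparisons within one projection, not
  as an absolute quantity.
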