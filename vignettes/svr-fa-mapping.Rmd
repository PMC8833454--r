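---
title: "Multivariate SVR mapping of white-matter FA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate SVR mapping of white-matter FA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrfa)
```

# The scientific problem

Multivariate lesion-symptom mapping asks which white-matter locations carry
a behavioural deficit. The approach implemented here regresses a continuous
behavioural score on voxel-wise fractional anisotropy (FA) sampled on a
tract-based skeleton, using a single multivariate model rather than one
test per voxel, so that the contribution of each voxel is estimated in the
context of all others. The fitted feature weights are then subjected to
permutation inference, false-discovery-rate control and cluster-extent
filtering, yielding a binary map of voxels whose FA reduction is reliably
associated with worse behaviour. Downstream, that map is quantified as a
structural disconnectome (streamlines of a normative tractogram that pass
through it, aggregated by parcellated region pair) and referenced against
probabilistic tract atlases by thresholded-overlap volume.

# The model

For $n$ subjects and $p$ skeleton voxels, let $X \in [0,1]^{n \times p}$
hold skeletonized FA and $y \in \mathbb{R}^n$ the behavioural scores. An
$\epsilon$-insensitive support vector regression with a **linear kernel**
is fit in the dual on the Gram matrix $K = XX^\top$; the primal feature
weights are recovered as

$$w = X^\top \alpha,$$

where $\alpha$ are the (signed) dual coefficients. The linear kernel is
essential: it makes $w$ a well-defined per-voxel quantity that can be
projected back into the volume as a topographic map. An RBF kernel is
available for prediction-only use, but voxel-wise inference refuses it.

## Hyperparameter selection

The SVR cost $C$ is chosen by repeated $k$-fold cross-validation (5 folds
$\times$ 5 repeats by default) scored on two axes:

* **model fit** — the mean across folds of the squared Pearson correlation
  between held-out predictions and observed scores;
* **weight reproducibility** — the mean pairwise Pearson correlation of the
  feature-weight vectors across all $k \cdot r$ training subsets.

Each axis is min–max normalized over the candidate grid and the two are
summed; the grid value maximizing the sum wins, with ties resolved toward
the smaller (more regularized) cost. The default grid is powers of two,
$2^{-20}$ to $2^{20}$. Selecting on reproducibility as well as fit reflects
that the deliverable is the weight *map*, not the predictions: a cost that
predicts well but reshuffles its weights across training subsets would
produce an unstable map.

## Permutation inference

Significance of each voxel's weight is assessed by refitting the SVR on
label permutations: the feature matrix is fixed and $y$ is permuted.
Because the Gram matrix does not depend on $y$, it is computed once and
each permutation costs only one dual solve, which keeps tens of thousands
of permutations tractable on one CPU. With $P$ sampled permutations the
p-value uses add-one smoothing,

$$p_v = \frac{1 + \#\{\text{permuted } w_v \text{ at least as extreme}\}}{P + 1},$$

so the smallest attainable p-value is $1/(P+1)$ and $p = 0$ never occurs.
For small cohorts ($n \le 8$) exact enumeration of all $n!$ permutations is
available; there the identity permutation is included in the reference set
and $p_v = \#\text{extreme}/n!$, again bounded away from zero.

**Tail choice.** The default tail is `negative`: a *lower* FA associated
with a *worse* score manifests as a negative weight when higher scores
encode better performance. When the planted or expected effect has the
opposite sign (as in the synthetic phantom below, where the score
increases with critical-region FA), `positive` is appropriate;
`two_sided` is available when no direction is privileged. The tail is an
explicit argument everywhere rather than a hidden convention.

**Cost reuse.** The permutation fits reuse the $C$ selected on the
observed data rather than re-optimizing per permutation. Re-optimizing
inside the loop would multiply runtime by the grid size while leaving the
null reference distribution essentially unchanged for grid-dominating
costs; holding the full pipeline fixed except the labels is the standard
compromise and is what this package does.

**Zero-variance voxels.** Voxels with no FA variance across subjects (for
example, complete lesion overlap) cannot carry evidence; they are retained
in the model but flagged and assigned $p = 1$.

## FDR and cluster-extent control

`fdr_select()` implements the Benjamini–Hochberg step-up literally: sort
the $m$ p-values, find the largest $k$ with $p_{(k)} \le kq/m$, and use
$p_{(k)}$ as the significance threshold (nothing is significant when no
such $k$ exists). The level is $q = 0.05$ by default. The implementation
is deliberately the textbook definition — the threshold itself is reported,
because the analysis's downstream maps are defined by it — and the test
suite cross-checks it against `stats::p.adjust("BH")` on random inputs.

Surviving voxels then pass a minimum-cluster-extent filter: connected
components (26-connectivity by default; 6 and 18 available) smaller than
20 voxels are removed. Small scattered clusters in permutation-based maps
are disproportionately false positives, and a 20-voxel floor is a common
reporting convention for skeletonized FA analyses.

## Covariate control

An optional covariate (for example a collinear second deficit score) can
be residualized out of the score, the features, or both, via ordinary
least-squares projection ($I - H$ with $H$ the covariate hat matrix)
before the SVR is fit. The default is no adjustment; the strategy is an
explicit config field so the choice is always visible in the run manifest.

# The synthetic phantom

Real patient imaging cannot ship with a package, so all end-to-end
behaviour is demonstrated and tested on a fully ground-truthed phantom:

* a **skeleton** of two orthogonal one-voxel-thick slabs in a cube
  (378 voxels at the default $16^3$ grid) standing in for a thinned
  white-matter skeleton;
* a **parcellation** of labelled blocks along one axis with one-voxel
  gaps, standing in for a cortical/subcortical region atlas;
* a contiguous **critical region** (10% of the skeleton by default) grown
  by breadth-first search from a random skeleton voxel;
* per-subject **spherical lesions** (radius 2.5–5.5 mm) that depress FA
  inside the lesion by a fixed drop (0.6 baseline, 0.35 drop, Gaussian
  noise SD 0.02);
* a **score** that is an affine function of mean critical-region FA plus
  noise, and a **covariate** constructed to correlate with the score at a
  target $\rho = 0.56$;
* an optional **tractogram** with exact planted region-pair streamline
  counts.

The phantom emulates the *structure* of a skeletonized-FA cohort analysis:
masked feature extraction, a spatially coherent effect, lesion-induced
signal loss, a correlated nuisance covariate, and streamline bookkeeping
with known truth. It does not emulate tissue physics: no partial-volume
effects, no spatially correlated noise, no registration error, no
Wallerian-degeneration gradients along tracts. Conclusions about
statistical calibration on the phantom therefore transfer to real data
only in so far as those omissions are benign; the phantom's purpose is to
verify the machinery, not to simulate pathology. The default problem
sizes ($16^3$ grid, ~400 skeleton voxels, 60–101 subjects, 500–1000
permutations in tests) are chosen so the full pipeline runs in minutes on
one CPU; they are package choices, not recommendations for real studies,
where 25,000 permutations and full-resolution skeletons are typical.

# Numerical choices worth knowing about

* **One Gram matrix.** $K = XX^\top$ is computed once per analysis and
  shared by the observed fit and every permutation fit.
* **Permutation tie tolerance.** Observed weights are computed as
  $X^\top\alpha$ per fit, while permutation weight blocks are computed as
  a single matrix product; BLAS accumulation order can shift exactly tied
  values by one ulp. Extremeness counts therefore use a relative tolerance
  of $10^{-8}(1 + |w_v|)$, which makes exact ties count as extreme
  regardless of evaluation order. Without it, exhaustive-enumeration
  p-values can disagree with an oracle by one count on tied permutations.
* **Lexicographic voxel order.** Masked voxels are enumerated sorted by
  $(i, j, k)$, not in R's column-major `which()` order, and the voxel
  index travels with every dataset and result so maps always project back
  to the right voxels.
* **Round-half-away-from-zero** world-to-voxel mapping, so points exactly
  halfway between voxel centres resolve deterministically and identically
  for positive and negative coordinates.
* **NIfTI round-trips** write `double` data with an sform-only affine, so
  a written-and-reloaded volume is bitwise identical to its source.
* **Binarization and floors are inclusive**: atlas probability maps are
  binarized at $\ge$ the threshold (0.4 default), and the overlap report's
  minimum-volume floor keeps overlaps at exactly the floor (20 mm³
  default) while dropping 19 mm³.

# Known limitations

* The permutation engine assumes exchangeability of subjects under the
  null; no block or covariate-restricted permutation schemes are provided.
* Only the linear kernel supports voxel-wise inference.
* Cluster-extent filtering uses a fixed voxel-count floor, not a
  permutation-calibrated cluster-size null.
* The disconnectome counts streamlines through a binary mask; no
  probabilistic weighting of streamlines is implemented.
* No spatial smoothing, TFCE, or total-lesion-volume regression is
  included.

# A minimal end-to-end run

```{r pipeline}
anatomy <- make_phantom_anatomy(seed = 1)
cohort <- make_phantom_cohort(anatomy, n_subjects = 40, seed = 2)
config <- mapping_config(c = 0.1, n_permutations = 200, tail = "positive",
                         perm_seed = 3)
result <- run_mapping(cohort$fa, cohort$scores, config)
result
glance(result)
```

```{r disconnectome}
pairs <- data.frame(region_a = c(1, 2), region_b = c(2, 3), count = c(12, 6))
tract <- simulate_tractogram(anatomy, pairs, seed = 4)
crossing <- streamlines_crossing_mask(tract, cohort$lesions[[2]])
dm <- build_disconnection_matrix(tract, crossing,
                                 assign_endpoints(tract, anatomy$parcellation))
report_edges(dm)
```
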