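---
title: "Similarity-stratified benchmarking of binding-affinity scoring functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-stratified benchmarking of binding-affinity scoring functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfstrat)
```

# The question this package addresses

A scoring function (SF) predicts the binding affinity of a protein–ligand
complex from structural descriptors; its scoring power is measured by the
Pearson correlation (Rp), Spearman correlation (Rs) and RMSE between
predicted and measured affinities (pKd/pKi units) on a held-out test set.
Machine-learning SFs outperform classical linear SFs on standard
benchmarks, and a recurring objection is that they merely memorize
training complexes similar to the test set. The way to interrogate that
objection is to *stratify* the training set by its similarity to the test
set and watch how each SF's scoring power responds.

`sfstrat` implements that analysis end to end: nested training-set
construction under three similarity metrics, re-calibration of three
classical multiple-linear-regression (MLR) SFs and five tree-ensemble
counterparts on every nested set, and evaluation of the resulting
performance curves, including crossing-point and sharp-leap detection.

# Nested training sets

Let OT be the full training set, TS the test set, and $s(p, q)$ a
similarity between a training complex $p$ and a test complex $q$. For a
cutoff $c$ the **dissimilar-first** (ds) nested set keeps the training
complexes whose similarity to *every* test complex is at most the cutoff,

$$\mathrm{NT}^{s}_{ds}(c) = \{\, p \in \mathrm{OT} : \forall q \in \mathrm{TS},\; s(p,q) \le c \,\},$$

and the **similar-first** (sd) set is the complement,
$\mathrm{NT}^{s}_{sd}(c) = \{\, p : \exists q,\; s(p,q) > c \,\}$. For a
*dissimilarity* $d(p,q)$ (pocket topology) the inequalities flip:
$\mathrm{NT}^{d}_{ds}(c) = \{\, p : \forall q,\; d(p,q) \ge c \,\}$ and
$\mathrm{NT}^{d}_{sd}(c) = \{\, p : \exists q,\; d(p,q) < c \,\}$. At any
cutoff the ds and sd sets partition OT, and each family is nested along
its cutoff grid. `nested_set()` and `build_family()` implement these
definitions by thresholding, per training complex, the maximum similarity
(or minimum distance) over the test set — provably equivalent to the
quantifier form, and property-tested against a brute-force evaluation.

Three similarity channels are supported:

* **protein structure** — a TM-score-like whole-complex alignment score in
  $(0, 1]$; ingest-only (alignment programs are external);
* **ligand fingerprint** — Tanimoto coefficient of hashed circular
  (ECFP4-style) fingerprints, in $[0, 1]$, computed by `tanimoto()`;
* **pocket topology** — city-block distance between fixed-length pocket
  shape/charge vectors, in $[0, \infty)$, computed by `cityblock()`.

The default sweep grids are 0.40→1.00 step 0.01 (protein, 61 cutoffs),
0.50→1.00 step 0.01 (ligand, 51 cutoffs) and 10.0→0.0 step 0.2 (pocket,
51 cutoffs). Grid points are generated from integer multiples of the
decimal step and rounded to the step's decimals, so a comparison like
$s \le 0.99$ is made against the exact printed cutoff; the similarity
values themselves are never rounded.

# Scoring functions

All eight SFs share one fit/predict contract and a registered
16-descriptor vocabulary: six X-Score terms, six Vina terms and four
Cyscore terms.

* `MLR::Xscore` — the X-Score consensus: three parallel ordinary
  least-squares fits sharing VDW/HB/RT and differing in the hydrophobic
  term (HP, HM, HS); the prediction is the mean of the three.
* `MLR::Vina` — the Vina quasi-MLR: the five empirical terms are divided
  row-wise by $1 + w_\mathrm{rot}\,N_\mathrm{rot}$ with the rotor weight
  fixed at the published value 0.05846 (not recalibrated), then OLS. The
  intercept is fitted on the transformed design, i.e. outside the
  normalization — an assumption, documented here.
* `MLR::Cyscore` — plain OLS on the four Cyscore terms.
* `RF::Xscore`, `RF::Vina`, `RF::Cyscore`, `RF::XVC` — random-forest
  regressions on exactly the same descriptor subsets (XVC = all 16), so
  any performance difference is attributable to the regression algorithm.
* `XGB::XVC` — gradient-boosted trees on the 16 hybrid descriptors.

OLS includes an intercept and is unconstrained in sign; rank-deficient
designs are an error naming the collinear columns, and fits are checked
against a normal-equations oracle to 1e-8 in the test suite.

**A note on the tree ensembles.** No random-forest or gradient-boosting
package is available in the target environment, so the ensembles are
implemented in this package in C++ (Rcpp): an exact greedy CART
regression-tree builder (variance-reduction splits, midpoint thresholds),
bagged with bootstrap resampling and per-split feature subsampling for
the RF family (defaults: 500 trees, mtry = ⌊p/3⌋, terminal node size 5 —
the RF-Score convention), and squared-loss shrinkage boosting with row
subsampling and depth-limited trees for the XGB family (defaults: 500
rounds, learning rate 0.05, depth 6, subsample 0.8; the source analysis
itself notes its boosting hyperparameters were probably suboptimal, so no
tuning is attempted). All stochastic fits draw from R's RNG, so a seed
makes them bit-reproducible; the depth-1 special case is tested against a
brute-force optimal-split oracle.

# Evaluation

`sweep_scoring()` trains every requested SF on every nested set and
scores it on the fixed test set. Minimum trainable sizes are p + 2 rows
for MLR and 10 for ensembles; smaller sets yield missing (`NA`) curve
points rather than errors. Ensemble fits are seeded per sweep point from
(global seed, cutoff index), making whole sweeps reproducible.

`find_crossing()` reports the first cutoff (in sweep order) where one
curve is strictly better than another (higher Rp/Rs, lower RMSE), plus a
`sustained` flag saying whether the win holds at every later comparable
cutoff. Both are reported because the verbal conventions in this
literature mix "surpassed at c" with "from c onwards" without a formal
rule. `leap_deltas()` returns per-increment changes, which is how "sharp
leaps" — outsized gains over the final (0.99, 1] near-duplicate band —
are located. Constant predictions have undefined correlations and
propagate as `NA`, never as 0.

# The synthetic benchmark

`generate_benchmark()` produces a fully self-contained world with the
statistical structure the stratified analysis assumes, so every stage
runs and is testable without any download. What it emulates, and how:

* **Latent protein families.** Complexes belong to `n_clusters` latent
  clusters. Descriptor centroids are drawn with sd 0.5 against
  within-family jitter whose per-complex scale is Unif(0.15, 0.9):
  energy descriptors overlap heavily across families, and families are
  internally heterogeneous, which spreads the similarity spectrum
  smoothly across the cutoff grid.
* **Affinity.** affinity = 6.5 + w·x + g + ε, clamped to the realistic
  pK range [2, 12]. The clamp exists to keep noisy, nonlinear worlds in a
  plausible span; in the exactly-linear diagnostic mode
  (`nonlinear_strength = 0`, `noise_sd ≤ 1e-6`) it is bypassed, because
  there the planted law must stay exactly linear to be recoverable and
  the clamp would corrupt the very signal that mode measures. w is a
  fixed 16-descriptor weight vector of norm ~1.05 (small enough that the
  clamp is essentially never active in realistic worlds either), balanced
  so the three classical SFs land in one Rp band, as the real classical
  trio does. g is a *cluster-specific interaction of two features*, centered
  per cluster: $g = \lambda\,(x_i x_j - c_i c_j)$ with the pair $(i, j)$
  drawn per cluster ($N_\mathrm{rot}$ excluded; its integer scale would
  dominate the product) and $c$ the cluster centroid. Centering makes g
  nearly orthogonal to any linear recalibration — a linear SF fitted on
  different nested sets stays essentially the same — while complexes from
  the same cluster, and above all near-duplicates, remain genuinely
  informative about it for a nonlinear learner. ε is Gaussian with
  `noise_sd` = 0.6 pK.
* **Protein-structure similarity.** A monotone map
  $s = \exp(-\alpha\,d)$ of latent distance, with $\alpha$ fixed a priori
  so the median distance of the 16-d standard-normal geometry maps to
  0.45 (an unrelated-fold TM-score scale). Cross-family pairs add
  exponential per-family and per-complex *structural divergences* (mean
  1.15 each): global structure separates unrelated folds much faster
  than energy descriptors do, and this largely decouples the low-cutoff
  strata from descriptor composition. The scales reproduce the realistic
  profile in which roughly 8% of training complexes fall below every
  test complex at the 0.40 cutoff.
* **Near-duplicates.** A `near_dup_fraction` (default 0.25, echoing the
  ~27% mass observed in the (0.99, 1] band on real data) of training
  complexes are twins of random test complexes (all latent coordinates
  copied plus sd-0.01 jitter), so they land in the (0.99, 1] band of
  their twin and drive the sharp-leap phenomenon.
* **Ligand and pocket channels.** Cluster-correlated random fingerprints
  (Tanimoto) and pocket vectors (city-block), with near-duplicates
  inheriting their twin's fingerprint/pocket up to small mutations. One
  latent cluster geometry drives all three channels, with
  channel-specific noise — three distinct but complementary views of the
  same complexes.
* **Planted truth.** `planted_truth()` exposes the generating weights,
  cluster labels, interaction pairs and twin map. With
  `nonlinear_strength = 0` and vanishing noise, an OLS fit on the full
  training table recovers the planted weights (to 1e-3 in the acceptance
  suite), and a noiseless linear world gives test Rp = 1.

What the generator does **not** emulate: real chemistry and 3-D
structures, the discreteness and censoring of experimental affinities,
correlated measurement error, CASF's cluster-sampling protocol, or any
relationship between descriptor names and physical meaning. A green test
therefore establishes that the *pipeline machinery* and the *qualitative
stratification phenomenology* behave correctly, not that any particular
real-data Rp value would be reproduced.

Two consequences of this construction are worth stating because they
shape how the generator's own invariants are tested. First, a CART
forest is not an efficient estimator of a smooth linear signal, so on a
purely linear truth a full-descriptor OLS beats any forest by a clear
margin at desk-scale n; a "forest ties linear" comparison is therefore
only meaningful when both models see the same descriptor subset. Second,
near-duplicate twins carry the *complete* affinity signal — including
the part borne by descriptors outside a model's subset — so any forest
beats a subset-restricted linear fit once twins are present, even with a
linear truth. The test suite asserts the forest-vs-linear tie in the
algorithm-isolating world (same subset, no twins) and the forest win in
the realistic near-duplicate world.

# What the stated world reproduces, and one honest gap

On the default benchmark (3000 training / 300 test complexes, 60
clusters, 500-tree forests, 5 seeds, 13-point protein grid), the
acceptance suite verifies: RF::XVC's Rp curve rises along the ds sweep
with its largest per-step increment at the final, near-duplicate
increment; at least one RF variant overtakes its matched classical
counterpart strictly below the grid maximum (which pair crosses earliest
varies with the realization, as it varies across real test sets); and
every classical curve's total variation is far below RF::XVC's.

The stricter absolute clause — classical total Rp variation below 0.02 —
is *not* met at desk scale and the corresponding expectation is left
failing rather than loosened. Two honest reasons: with smallest nested
sets of ~250–450 complexes and a 300-complex test set, OLS coefficient
noise alone contributes ~0.01–0.02 of apparent variation; and each
classical SF sees only a subset of the descriptors, so the cluster-mean
shadow of its missing descriptors genuinely improves as test-family
complexes enter training. At the real benchmarks' scale (4154/318,
smallest set 334) the same analysis shows variation of 0.006–0.024.
Reproducing sub-0.02 flatness at desk scale while keeping the RF-vs-MLR
crossing below the grid maximum was not achievable: the same model
misspecification that gives the forest its mid-grid edge is what moves
the linear fits.

# Numerical and design choices

* Ids are lowercased on ingest; matching across tables is by lowercase id.
* Similarity matrices are stored dense; the realistic upper bound
  (318 × 4154) is ~1.3M cells.
* Empty nested sets are legal; downstream training records missing
  points.
* Tanimoto of two empty fingerprints is 0, not 1: an atom-free ligand
  carries no evidence of similarity.
* `matrix_agreement()` compares with an inclusive threshold
  ($|a-b| \le t$).
* Ties in CART splits (several splits attaining the optimal variance
  reduction) are broken by scan order; only the attained optimum is
  contract-tested.
* The pipeline (`run_pipeline()`) validates its config before any
  compute, rejects unknown keys, and writes a manifest with a config
  hash and seed; re-running a config reproduces identical numeric
  outputs.

# Known limitations

* The exact on-disk layout of externally deposited similarity matrices
  varies; the reader accepts one labeled-matrix dialect (first column =
  test id, remaining columns labeled by training id), and other layouts
  must be converted.
* The XGB-style booster implements the classic gradient-boosting recipe
  (shrinkage + subsampling + depth-limited exact-split trees), not the
  regularized second-order objective of modern libraries.
* Crossing detection is reported on the sweep grid; no interpolation
  between cutoffs is attempted.
* Leave-cluster-out cross-validation and soft-overlap redundancy removal
  are out of scope.
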