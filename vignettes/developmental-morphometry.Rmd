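---
title: "Developmental morphometry of basal dendritic arbors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental morphometry of basal dendritic arbors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrodev)
```

This vignette is the package's account of its methods: the measurements,
the stability classifier, the ordination and validation machinery, the
synthetic cohort generator, and the design decisions taken where the
problem left genuine freedom.

## The scientific question

Pyramidal-cell basal dendrites change shape throughout development. Two
kinds of change should be distinguished: features that mature early and
then *stabilize* (topological organization — how often branches split,
how unbalanced the subtrees are, how tortuous branches run), and
features that *keep changing* (the physical size of the arbor — total
length, spatial extents, dendritic field area). The package operates on
cohorts of SWC reconstructions labelled by age group and cortical area,
and separates these two regimes feature by feature.

## SWC input and its normalization

SWC files are 7-column text (`id type x y z radius parent`). The parser
tolerates space and tab delimiters, keeps `#` comments as metadata,
reorders nodes so parents precede children (file order is not assumed
topological), and rejects duplicate ids, dangling parents, cycles and
multi-root files with the offending line in the message.

Two normalization rules are applied at parse time:

* **Multi-node somas** (several type-1 nodes) are collapsed to a single
  root at the first soma node; children of the other soma nodes are
  re-parented onto it. Soma-internal geometry therefore never enters
  length or hull computations, which is the right behavior when only the
  basal skirt is analyzed. Archive conventions for multi-point somas
  vary and are rarely documented; collapsing is our choice and is the
  one that leaves the dendritic measurements invariant to how the soma
  outline was digitized.
* **Multifurcations** (k > 2 children) are accepted and counted as
  k − 1 bifurcations. For partition asymmetry they contribute the k − 1
  values of a nested first-child-versus-rest decomposition, and for the
  remote bifurcation amplitude the k − 1 consecutive-pair angles. The
  generator only produces binary trees, so this convention is exercised
  by hand-built fixtures, not load-bearing for any headline result; it
  is reported in `count_topology()$multifurcations` as a data-quality
  diagnostic.

## The 15 features

Definitions follow the standard morphometry vocabulary
(`?compute_feature_vector` and the README table). Points that needed a
decision:

* **Partition asymmetry** at a (1,1) bifurcation is 0/0 in the formula
  \|n₁−n₂\|/(n₁+n₂−2); we score it 0 ("maximally balanced"), the common
  convention, with `terminal_bif = "exclude"` available.
* **Width/height/depth** are the coordinate ranges after rotating the
  node cloud onto its principal axes, sorted in decreasing order. This
  makes the extents orientation-independent ("adjusted"), at the price
  of not being literally the file-frame bounding box.
* **Fractal dimension** is the OLS slope of log path distance on log
  Euclidean distance, one point per non-soma node, soma and
  zero-distance nodes excluded. The log base cancels from the slope.
* **Convex hull area** is computed on the raw (x, y) projection by
  default — reconstruction conventions usually place the slice plane
  there — with `plane = "pca"` available to project onto the first two
  principal axes instead. The choice matters: the xy hull is *not*
  invariant to out-of-plane rotations, and results from differently
  oriented archives should use the PCA plane.
* **Distances from soma** (`pathDistance`, `euclidean_Distance`) are the
  maxima over nodes, not means; the maximum is the standard "distance
  from soma" summary and respects `path ≥ euclidean` pointwise.
* Undefined features (no bifurcation → no asymmetry or amplitude; fewer
  than 3 usable nodes → no regression slope) are carried as `NA`, never
  as 0, and rows with `NA`s are dropped with a warning when the feature
  matrix is assembled (no imputation).

Every feature is checked in the test suite against an independent
naive-traversal oracle (plain recursion, gift-wrapping hull, eigen on
the explicit covariance) on 200 random trees at 1e-9 relative tolerance,
and the whole vector is checked for scale equivariance (lengths × s,
areas × s², dimensionless features fixed) and rigid-motion invariance.

## Preprocessing

* **Outliers**: boxplot rule — a neuron is removed when any feature
  falls outside [Q1 − k·IQR, Q3 + k·IQR], k = 3 by default, fences
  computed per cortical area (areas differ strongly in absolute scale).
  Features whose IQR is zero (discrete counts concentrated on one value)
  have no usable box and are skipped; without this rule a count feature
  with a degenerate box flags every off-mode neuron. The achieved
  removal fraction is reported, not forced to any preset figure.
* **Scaling**: z-scores with the population (divide-by-n) standard
  deviation, matching the behavior of the standard scaler used in the
  field's Python stacks; centers and scales are stored so the transform
  inverts exactly and so a scaler fitted on training rows can be applied
  to held-out rows.
* **Correlation pruning**: for each pair with Pearson \|r\| above 0.8
  exactly one member is dropped. Rather than dropping "randomly" (which
  is irreproducible), a keep-list decides deterministically; the default
  keeps `pathDistance` over `euclidean_Distance` and `n_bifs` over
  `n_branches`, the 13-feature working set this analysis tradition
  retains. Ties outside the keep-list drop the later column. The outcome
  is invariant to row order.

Inside validation, scaling is fitted on training rows only by default to
avoid leakage; `paper_exact = TRUE` restores the scale-then-split order
some studies use. On synthetic data the difference is well under the
seed-to-seed spread.

## The stability classifier

For each feature and a pair of consecutive age groups, both samples are
binned on a common equal-width grid spanning their pooled range
(20 bins by default) and compared by the **L1 distance between relative
frequency histograms**, Σᵢ\|pᵢ−qᵢ\|. This distance lives on [0, 2]: 0
for identical binned distributions, 2 for disjoint supports, which makes
1 — the half-range point — the natural cutoff separating *stable*
(< 1) from *varying* (≥ 1). The distance is twice the total-variation
distance of the binned distributions, is symmetric, and can only grow
under common bin refinement (both properties are tested).

The convention is to compare the two oldest consecutive groups
(3.5 vs 7 months, or 7 months vs adult where adult data exist): a
feature stable across that interval has plausibly finished maturing.

Caveats the user should know:

* The distance depends on the bin count; reports record the edges used.
  With very few bins everything looks stable (one bin gives distance 0);
  with very many bins sampling noise inflates the distance. Twenty
  equal-width bins is a reasonable default at cohort sizes of tens to
  hundreds.
* Histograms are computed on z-scored features by default, consistent
  with running the classifier on the scaled analysis matrix. Because
  z-scoring is a per-feature affine map and the grid spans the pooled
  range, calls are identical on raw units unless a feature's two groups
  differ only through the pooled scaling.
* The classifier sees distribution shape, not meaning: a 5% size shift
  between groups is far below the cutoff at realistic n, so "stable"
  means "not detectably different at this binning", not "biologically
  finished".

## Ordination, clustering, validation

* **Dual PCA**: principal components are fitted separately on the stable
  subset and the varying subset (this is the analysis's centerpiece:
  separation of age groups in stable-feature space indicates early
  maturation, separation in varying-feature space indicates ongoing
  growth). Loadings carry a deterministic sign convention — the
  largest-magnitude loading of each component is positive — so plots
  reproduce across runs and BLAS builds.
* **Group polygons** are plain convex hulls of each age group's
  (PC1, PC2) scores. Hulls of the clustering partition instead of the
  age labels are a supported variant (pass cluster assignments as
  `groups`); the per-age-group hull is the default because it answers
  the question actually asked (do *ages* separate?).
* **Ward clustering** uses Euclidean distances and the `ward.D2`
  criterion on the components that cumulatively explain 95% of variance.
  Heights are monotone; two singletons merge at their Euclidean
  distance; linkage exports to Newick via `ape`.
* **SVM validation**: stratified 70/30 hold-out and stratified 10-fold
  CV, age group as the class, with and without PCA reduction to the
  95%-variance components (PCA fitted on training rows only). The kernel
  is unspecified in this analysis tradition; the default is RBF with
  cost 1, both configurable. Conclusions drawn from validation in the
  test suite use synthetic separable data, so the kernel choice is not
  load-bearing.

## The synthetic cohort generator

`generate_tree()` grows a binary tree: each branch is a short random
walk (Poisson number of steps, Gaussian step lengths, direction drifting
by a `tortuosity` perturbation per step); at the branch end growth
bifurcates with probability `bifurcation_prob · prob_decay^order` into
two daughters separated by a Gaussian opening angle; finally all
coordinates are multiplied by `radial_scale`. Defaults (4–6 stems,
branch probability 0.9 decaying by 0.6 per order, ~12 μm steps,
tortuosity 0.15, 70° openings, z flattened to a quarter) give arbors
with ~10–20 bifurcations, maximum order 3–5, total length 1–3 mm and
dendritic fields of tens of thousands of μm² — order-of-magnitude
realistic for a layer III basal skirt, which is all that is claimed.

The point of the generator is **independent steerability**: the scale
knob moves every size feature and nothing else; the branching knobs move
the topology counts and nothing else. That is what makes the stability
classifier testable — a cohort differing only two-fold in scale must
come out size-varying/topology-stable, and a cohort differing in
branching probability must flip `n_bifs` and `branch_Order` to varying.
Both recoveries are asserted in the suite.

`default_cohort_spec()` shapes the demo cohort like a primary-visual-
cortex developmental sample: five age groups of 25/41/28/33/105 neurons
with radial scales 1.30/1.15/0.97/1.05/1.00 — largest at 2 days,
shrinking below adult size at 3.5 months, a transient rebound at
7 months. Topology parameters are identical across ages, so the
generator's ground truth is: all topology features stable everywhere,
size features shifting along the trajectory.

**What the generator does not emulate.** Real reconstruction cohorts
carry batch effects, tracing artifacts, age-dependent *variance* (not
just location) changes, spines, and non-binary branch points; none of
these are modelled. Two consequences matter when reading test output.
First, the default cohort's 7-month→adult size step is 5%, far below
the cutoff, so the demo's stability table calls *everything* stable at
that pair — real archive data separate size features there because the
real distributions differ in more than location. Second, with purely
scale-steered groups the SVM reaches ~45% five-class accuracy, not the
~85% reported on real data, because three of the five synthetic groups
are nearly identical by construction. Passing tests therefore
demonstrate that the machinery measures and classifies correctly, not
that real cohorts behave like the generator.

## Numerical choices and degenerate inputs

* Histogram bins are half-open [a, b) with a closed final bin; every
  in-range value lands in exactly one bin.
* A constant feature cannot be z-scored; the error names the feature.
  Constant columns likewise yield `NA` correlations, which the pruner
  treats as "not correlated" rather than dropping blindly.
* Collinear node projections give hull area 0 with a warning; fewer than
  3 usable regression points give `NA` fractal dimension; zero-length
  branches and zero-length remote vectors are excluded (warned) from
  contraction and amplitude.
* The fractal-dimension estimator regresses log path on log Euclidean
  distance. At high tortuosity the Euclidean regressor becomes noisy and
  classical errors-in-variables attenuation can push the slope *below*
  1 even though path ≥ Euclidean pointwise; the property "tortuous
  slope ≥ straightened slope" is only tested at mild tortuosity, and
  users comparing very tortuous arbors should treat the slope as a
  relative, not absolute, complexity index.
* PCA on rank-deficient input reports 0% variance beyond the rank;
  `prcomp` handles the decomposition, with the sign convention applied
  on top.
* Per-tree seeds are derived from the cohort seed by counter, so any
  tree regenerates in isolation and cohorts are reproducible
  end-to-end; `run_full_analysis()` is byte-identical across reruns of
  the same config (the summary embeds a config hash).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic
cohorts sized for quick, stable statistics: 200 random oracle trees of
up to 50 nodes, stability recovery at 200 neurons per group,
correlation-structure checks at 400–1000 rows, the PCA variance check at
10⁵ points, chance-level validation at 500 rows, and the full pipeline
at the 232-neuron five-group default cohort. These sizes are the
package's own choice of demonstration scale; all of them rerun in well
under a minute each on one core.

## Known limitations

* The xy-plane hull is frame-dependent (see above).
* Stability calls are binning-dependent by construction; report the bin
  count alongside any call.
* The generator's biological realism is deliberately minimal; it is an
  instrument for validating the pipeline, not a model of dendritic
  development.
* `fetch_neuromorpho()` needs network access and sparse archive
  metadata handling is best-effort (rows with unparseable age are
  flagged `NA`, never guessed); it is excluded from the offline test
  suite.
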