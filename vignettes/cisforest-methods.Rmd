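---
title: "Lesion shape radiomics and oblique forests for CIS-to-MS prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion shape radiomics and oblique forests for CIS-to-MS prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cisforest` predicts conversion from a clinically isolated syndrome (CIS)
to multiple sclerosis from baseline lesion segmentation masks. This
vignette is the package's own account of what it computes, which knobs
matter, which design decisions were genuinely open, and what its tests do
and do not establish.

## The model pipeline

The input per patient is a pair of co-registered 3D arrays — a FLAIR-like
intensity volume and a binary lesion mask — plus an outcome label
(converted to MS within three years or not) and, for the clinical
benchmark, a per-lesion anatomical location label. The pipeline has four
stages:

1. **Lesion features.** Each 26-connected component of the mask is one
   lesion. Its geometry is summarised by the voxel count $n$, volume
   $V = n \cdot v$ (with $v$ the voxel volume in mm³), triangulated
   surface area $A$, Wadell sphericity
   $\Psi = (36\pi V^2)^{1/3}/A$ (equivalently $\pi^{1/3}(6V)^{2/3}/A$;
   1 for a sphere, smaller for elongated shapes), and the surface-volume
   ratio $SVR = A/V$. Intensity inside the lesion is summarised by the
   skewness and (non-excess) kurtosis of the voxel intensities and the
   Shannon entropy, in bits, of their 64-bin histogram.
2. **Aggregation.** Patients have different lesion counts, so the
   classifier needs fixed-length vectors: per base feature the minimum,
   maximum, mean and population standard deviation over the patient's
   lesions, plus the total lesion volume and the lesion count in every
   set. The shape set (volume, surface area, sphericity, SVR) has 18
   entries, the intensity set (skewness, kurtosis, entropy) 14, the
   combined set 30.
3. **Oblique random forest.** Bagged trees with *linear multivariate*
   node splits: at each node `mtry` features are drawn without
   replacement, the ±1-coded labels are regressed on them by ridge
   (L2-penalised) least squares for each penalty in a grid, and the
   threshold on the ridge projection is placed at the sorted-projection
   midpoint minimising Gini impurity. `mtry` and `ntree` are tuned by
   grid search on the out-of-bag error.
4. **Evaluation.** Stratified 3-fold cross-validation with tuning strictly
   inside the training folds; confusion matrices and a full
   diagnostic-statistics suite (below); the McDonald-2010
   dissemination-in-space rule — predict conversion iff lesions involve
   at least two of {periventricular, juxtacortical, infratentorial,
   spinal} — as the clinical benchmark; exact McNemar tests between
   classifiers.

## Surface extraction: the one numerically delicate step

Everything downstream of the surface area (sphericity, SVR) depends on how
the discrete boundary is turned into an area, so this choice is documented
in detail.

The package triangulates the iso-0.5 surface marching-cubes style, using a
tetrahedral decomposition of each grid cell (six tetrahedra per cell, 0–2
triangles per tetrahedron, vertices linearly interpolated at the iso
level). The decomposition produces a consistent closed surface without the
classic 256-case cube table, which is easy to get subtly wrong.

On a *raw binary* field all interpolated vertices sit at voxel midpoints
and the triangulation reproduces the voxel staircase, overestimating the
area of smooth objects by roughly 28% regardless of size. The package
therefore pre-filters the padded binary crop with a 3×3×3 mean kernel, so
interpolation tracks the true boundary: for digital balls the area error is
then −1.6% at radius 10 voxels and within ±0.2% above radius 15, and ball
sphericity lies in [0.99, 1.08] over radii 5–25, converging to 1.

The pre-filter has a failure mode: an object only one or two voxels thick
is eroded below the iso level and its smoothed surface collapses. The
filter is therefore *scale-aware*: the smoothed surface is used only when
it retains at least 60% of the raw staircase area — the error-balanced
switchover given the staircase's +28% bias — and the raw surface is used
otherwise. In practice lesions above roughly 200 mm³ on the default grid
take the smoothed branch and very small lesions the raw one. Consequences
worth knowing:

* absolute sphericity values of *small* lesions carry a consistent
  negative bias (the staircase inflates $A$); group *contrasts* are
  preserved, which is what the classifier uses;
* the branch switch introduces a mild discontinuity in $A$ across lesion
  sizes; it is shared by all patients and groups.

Surface area is invariant to how much background padding a crop carries
(crops are re-padded internally), and scales exactly with physical voxel
dimensions.

## The synthetic cohort: what it emulates, and what it does not

No patient data ship with the package; a generator
(`cohort_spec()` / `generate_cohort()`) provides the study conditions the
models are exercised under. Its defaults are the cohort structure the
method is aimed at: 84 patients, 66 of them converters (79%); mean
single-lesion volume 135 mm³ in converters vs 71 mm³ in non-converters,
with single-lesion volumes truncated to the 22–671 mm³ range; converter
lesions markedly less spherical (group targets 0.78 vs 0.927); a
96×96×64 grid at 1×1×1.5 mm echoing a 3D FLAIR acquisition.

Design of the generator, with the open choices made explicit:

* **Shape family.** Triaxial (prolate) ellipsoids with lognormal volumes
  and group-specific elongation: the simplest family that controls volume
  and sphericity independently. The group elongation is obtained by
  numerically inverting the analytic prolate-spheroid sphericity at the
  group target, with lognormal jitter (sdlog 0.15) per lesion. Because
  voxelization and the surface estimator bias small-lesion sphericity
  downward, the *extracted* group means (≈ 0.77 vs ≈ 0.68 at the default
  spec) sit below the analytic targets; the ordering and separation are
  what the generator guarantees (and what the tests assert).
* **Volume calibration.** Per-lesion volumes are truncated-lognormal
  (sdlog 0.6) on the observed range; the meanlog is solved numerically so
  the *truncated* mean equals the group target, rather than hand-tuned.
  Rasterisation adds a small negative bias for the smallest lesions, so
  extracted group means land within a few percent of target (well inside
  the 15% recovery tolerance the tests use).
* **Lesion counts.** Uniform on 1–15 per patient, identical in both
  groups: no per-patient count distribution is published, and keeping the
  groups identical here ensures the classifier's signal comes from size
  and shape, not count.
* **Locations.** Labels are assigned from grid regions — an inferior slab
  (infratentorial), a central box (periventricular, a ventricle proxy),
  the outer shell (juxtacortical) — with a 2% chance of a spinal label.
  The DIS rule needs labels, not anatomy; no atlas is involved.
* **Intensity.** Background N(100, σ²), lesion N(160, σ²), σ = 10
  (arbitrary units). Both groups share the intensity model: intensity
  features are deliberately *uninformative about shape* in the synthetic
  cohort, though total volume and count (present in every feature set)
  still make the intensity model much better than chance.
* **Geometry invariants.** Lesions keep ≥ 2 voxels of boundary clearance
  and a ≥ 1-voxel margin from each other, so 26-connected components never
  merge and surface extraction is always well defined. Lesion ids are
  assigned in the extractor's own (min z, min y, min x) order so location
  labels line up after a disk round trip.

What the generator does **not** emulate: anatomical lesion distributions,
bias fields, partial-volume effects, segmentation noise, or any
correlation between intensity texture and outcome. Passing tests on this
cohort therefore demonstrate that the pipeline's machinery is correct and
that it detects size/shape contrasts of the published magnitude — not that
the published real-data accuracies transfer.

## The oblique forest: numerical choices

* Labels are coded −1/+1 for the node ridge regression; the intercept is
  unpenalised. The default penalty grid is $10^{-3} \ldots 10^2$ (decade
  steps), searched per node; the penalty keeps node fits defined under
  collinearity (duplicated or correlated features).
* Features are z-scored with training-set statistics before fitting, so a
  single penalty grid is meaningful across units (mm³ next to unitless
  sphericity); constant features get unit scale.
* Split quality is Gini impurity over candidate thresholds at midpoints of
  consecutive distinct sorted projections; a node becomes a leaf when
  pure, below `min_node_size` (default 2), at `max_depth` (default
  unlimited), or when no threshold strictly reduces impurity.
* Vote ties (exactly half the trees) predict conversion — the majority
  class and the asymmetry the DIS benchmark also has. Leaf ties likewise.
* Tuning scans `mtry ∈ {3, ⌊√p⌋, 7}` × `ntree ∈ {100, 200, 300}` on OOB
  error with ties broken toward smaller `ntree`, then smaller `mtry`; one
  RNG stream covers the whole search, so tuning is reproducible from one
  seed.
* The importance score follows the bootstrapped node-logistic-regression
  counting rule (+1 if a subset feature's Wald p < 0.05 at an internal
  node, −1 otherwise; 100 bootstrap refits by default, per-iteration mean
  reported). The node model is multivariate on the node's `mtry` subset;
  a univariate-per-feature variant is available. A node whose logistic
  fit fails to converge — perfect separation, the maximally informative
  case — counts +1 for all its subset features and is flagged.
* All randomness (bootstraps, feature subsets) draws from R's RNG, so
  `set.seed()` makes fits, tuning and importance bit-reproducible.

## The statistics suite

With TP/FP/TN/FN counts (positive class = conversion, $n_1 = TP+FN$,
$n_0 = TN+FP$):

* accuracy, sensitivity, specificity with **Clopper-Pearson** exact
  intervals (Beta quantiles; closed at 0/1 boundaries);
* PPV/NPV with **logit intervals**; the default variance is the
  prevalence-aware form
  $\mathrm{var}(\mathrm{logit\,PPV}) = \frac{1-se}{se\,n_1} + \frac{sp}{(1-sp)\,n_0}$
  (and the NPV analogue), which reproduces the published benchmark
  intervals; the plain binomial-logit form is available. Degenerate
  estimates (0 or 1) get a 0.5-per-cell continuity adjustment so the
  interval stays inside (0, 1);
* **balanced accuracy** $(se+sp)/2$ with the Brodersen posterior interval:
  $S \sim \mathrm{Beta}(TP{+}1, FN{+}1)$,
  $P \sim \mathrm{Beta}(TN{+}1, FP{+}1)$ independent, the distribution of
  $(S+P)/2$ obtained by numerical convolution of the discretised densities
  (20001 cells per density) and reported as equal-tailed quantiles;
* the **diagnostic odds ratio** with the Glas interval
  $\exp(\ln DOR \pm z\sqrt{1/TP+1/FP+1/TN+1/FN})$; a zero off-diagonal
  cell yields $+\infty$ unless the Haldane 0.5 correction is enabled
  (requesting the interval with a zero cell without it is an error);
* **McNemar's test** on discordant pairs, exact binomial by default
  (two-sided, $p = \min(1, 2P(X \le \min(b,c)))$) — appropriate for the
  small discordant counts these comparisons produce — with the
  corrected-χ² variant as an option.

Reproduction of the published benchmark table (the four confusion matrices
of the 84-patient cohort) is part of the acceptance tests: 78 of 84 table
cells match exactly at the printed 2-decimal precision. The six exceptions
are documented in the test: two are PPV upper bounds, where the published
logit-interval variant is ambiguous (held to ±0.02), and four sit exactly
one unit of the last printed digit away from what exact arithmetic of the
stated formulas yields (e.g. a published 0.81 where the exact value 0.8158
rounds to 0.82); no single rounding convention reproduces them, so they
are held to one printed ulp.

## Cross-validation layout

The published protocol divides the cohort randomly into three subsets;
this package stratifies by outcome by default, because with only 18
non-converters an unlucky non-stratified split can leave a training fold
with almost no negatives (a non-stratified mode exists, and re-seeds
itself if a fold loses a class entirely). Tuning — including its OOB grid
search — runs strictly inside each training fold, and only pooled
out-of-fold predictions are evaluated.

## Problem sizes used by the tests

Unit tests run on miniature cohorts (16 patients, 64×64×48 grids) to keep
the suite fast; the acceptance tests run the full default spec: one
84-patient cohort for volume recovery, twenty replicate 84-patient cohorts
for the shape-vs-intensity comparison (shape must win in ≥ 80%), and 100
seeded importance runs for the planted-signal rank check (≥ 95 must rank
the planted feature first). These sizes are the package's chosen
trade-off between statistical strength and a test suite that runs in a
few minutes.

## Known limitations

* Sphericity and SVR of lesions near the resolution limit are dominated by
  voxelization; absolute values there should not be compared across
  resolutions (the same caveat applies to any mesh-based radiomics at
  2D-slice resolutions).
* The generator's group contrast is idealised; real cohorts add
  segmentation noise and anatomy that the synthetic tests cannot probe.
* The forest is binary-class only, reports no calibrated probabilities,
  and the published real-data accuracies are not reproducible without the
  original images — the tests assert directional and structural
  properties instead.
* The importance score is a count, not an effect size; its scale depends
  on tree depth and `n_bootstrap`.
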