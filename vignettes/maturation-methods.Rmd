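---
title: "Quantifying cell-type maturation in developmental single-nucleus atlases"
author: "maturatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-type maturation in developmental single-nucleus atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Developmental single-nucleus RNA-seq atlases sample the same brain region
at an ordered series of ages — here the vocabulary E16, E18, P0, P4, P10,
P18, P28 and P65, with the last stage treated as the adult reference — and
ask, for every transcriptomic cell type, *how* and *when* it acquires its
adult expression state. maturatlas implements a coherent set of estimators
for that question:

* **Maturation distance** (`distanceTrajectory()`): within one cell type,
  cells of all ages are log-normalized, reduced to 2,000 highly variable
  genes, embedded by PCA, and summarized by per-age centroids over the
  smallest number of components explaining 20% of variance (capped at
  100). The Manhattan (L1) distance between each age's centroid and the
  adult centroid declines toward zero as the type matures.
* **Monotonization and trajectory classes** (`monotonize()`,
  `classifyTrajectory()`): occasional upward excursions (transient
  programs such as axon-guidance waves) are clamped by a running minimum;
  the monotone series is classified by how few consecutive-age steps,
  taken largest-first, carry 90% of the total decrease — stepwise
  (1–2 steps, class 3), intermediate (3, class 2), gradual (4 or more,
  class 1).
* **Nearest-neighbour maturity** (`nnMaturity()`): the fraction of each
  age's k = 50 nearest neighbours (Euclidean, same reduced space) that
  are adult cells; an ordination-free corroboration of the distance
  trajectory.
* **Label transfer** (`trainReference()`, `predictionScores()`,
  `assignLabels()`, `mapAgesIteratively()`): younger cells are labeled
  from older ones, oldest first, by distance-weighted k-nearest-neighbour
  votes (k = 30) in a 150-component reference projection. A cell is
  assigned when its top score exceeds 0.8, or exceeds 0.5 while at least
  doubling the runner-up; everything else stays unassigned and is dropped
  from per-cell-type statistics.
* **devDEGs** (`pseudobulkBySample()`, `devdegTest()`, `fitTrend()`,
  `clusterTrends()`, `classifySharing()`, `eigentrend()`,
  `refinementScore()`): replicate-aware time-course differential
  expression on per-sample pseudobulk log-CPM with an intensity-trended
  empirical-Bayes variance and a moderated F-test of the age factor
  (FDR < 5%), with the standard `filterByExpr` expression filter — this
  limma-trend form measured markedly better null calibration than
  observation-level precision weights at the atlas design's sample sizes;
  penalized cubic spline
  trends on the age-rank axis; Ward clustering of min–max-normalized
  trends; sharing classes at the >70% / <20% detection boundaries; the
  refinement score as the fraction of expressed gene-by-cell-type
  combinations changing between P10 and P65.
* **Group contrasts** (`groupDistanceContrast()`): sexes or genotypes are
  compared per cell type by all pairwise Manhattan distances between
  per-sample centroids in the jointly fitted reduced space; the effect
  size is mean(inter)/mean(intra) and a two-sided t-test compares the two
  distance sets, BH-adjusted across cell types for genotype screens and
  read at raw p < 0.05 for sex contrasts.
* **Pseudotime** (`fitPseudotimeCurve()`, `projectCells()`,
  `delayTest()`, `estimateDelay()`): a principal curve — iterated
  project-then-smooth with cubic smoothing splines, initialized on the
  first component — fitted per cell type in a 20-component space on
  control cells; held-out (mutant) cells are projected onto it, and
  per-age t-tests across cell-type mean pseudotimes detect developmental
  delay. `identifyCoreMaturationGenes()` derives the shared maturation
  programme (log2FC > 0.5 from the pooled E16/E18 stages to adult,
  expressed in at least 30% of sampled adult cells, on balanced
  10-cell-per-type subsamples).

# The synthetic study design

`syntheticSpec()`/`generateDataset()` emulate the atlas design: eight
ordered stages, two samples per sex per age, discrete cell types
separated by marker genes (8-fold baseline multiplier), log-normal
library sizes calibrated to the study scale (thousands of UMIs per
nucleus; the default mean lands within a few percent of 5,276), and
negative-binomial counts with variance mu + mu^2/theta. theta = 10 by
default — the mild overdispersion typical of UMI counts — with Poisson as
the theta -> infinity limit.

Age enters through a per-cell-type *maturation schedule*: a
non-decreasing map from age rank to progress in [0, 1]. Trend genes
follow the schedule in natural-log space — linearly up or down
(amplitude log 4 over the full range by default, the same 4x scale used
in the power checks), as a step when progress crosses a gene-specific
threshold, or as a transient Gaussian bump with a random sign. Mutant
cells run the same schedule with the age index shifted back by
`delayStages` (clamped at the first stage), so a mutant at stage j is
*exactly* a control at stage j − delay. Expected expression is
composition-normalized per condition; a cell's expected total equals its
drawn library size.

Design choices worth stating explicitly, with their reasons:

* **Schedules plateau one stage before adult.** The final age step
  carries zero progress, so a one-stage-delayed clock coincides with the
  undelayed one at the last stage. This reproduces the transience of the
  delay phenotype — strong at intermediate ages, gone by adulthood — and
  makes the "non-significant at the final age" expectation exact rather
  than approximate.
* **Planted classes are defined at the measurement.** The measured
  trajectory always ends with a small step into the adult self-distance
  of exactly zero (the centroid sampling floor). The largest-first 90%
  count therefore includes that floor step. Schedules plant one dominant
  step for stepwise types (measured k = 2), two for intermediate types
  (k = 3) and an even spread for gradual types (k >= 5); a short
  calculation shows this labeling is stable across the whole realistic
  signal-to-floor range, whereas a three-big-step schedule can never
  measure as three steps once a floor exists.
* **Trend genes are drawn from the better-expressed part of the gene
  pool** (above the 40th baseline percentile): age-regulated genes must
  be quantifiable, and at very low counts the log transform flattens
  their planted dynamics.
* **Transient programs get random signs** so they do not form a single
  coherent PCA axis; a coherent transient axis inflates mid-age distances
  and warps step sizes (diagnosed by per-component distance
  decomposition).
* **Uniform two-samples-per-sex design at every age.** The real design
  had one sample per sex at the earliest embryonic stage; the generator
  keeps the design balanced, and the devDEG test instead enforces the
  at-least-two-samples rule per age where it matters.

What the generator deliberately does *not* emulate: doublets, ambient
RNA, batch chemistry, spliced/unspliced layers, correlated cell-state
factors beyond the maturation axis, and cell-type abundance differences
(counts per type are uniform and configurable). Passing tests therefore
demonstrate correctness of the estimators under the stated generative
model, not robustness to those artifacts.

# Numerical choices

* PCA standardizes genes (centering always, unit variance by default;
  constant genes get scale 1). Problems whose smaller dimension is at
  most 600 are solved exactly via the smaller-side Gram matrix; larger
  ones use a seeded randomized range-finder SVD (10 oversamples, 2 power
  iterations), deterministic given its seed. Variance fractions divide by
  the total variance of the standardized matrix, so the 20% rule behaves
  identically under both solvers at the accuracy that matters.
* The 20%-of-variance rule frequently caps at 100 components on flat
  spectra — the intended behavior of the cap.
* Highly variable genes: dispersion (variance/mean of log-normalized
  expression) standardized within 20 equal-frequency mean bins; ties
  broken by gene id; never-expressed genes excluded.
* Module scores draw 100 control genes per set gene from 24
  equal-frequency expression bins (seeded), over expressed genes only, so
  scores are invariant to padding with silent genes.
* Age z-scores use the population (divide-by-n) standard deviation and
  map an all-equal series to zeros.
* The principal curve smooths each coordinate with `smooth.spline` at 5
  effective degrees of freedom (the usual principal-curve smoother; GCV
  smoothing can diverge under projection feedback), renormalizes arc
  length every iteration,
  evaluates 100 polyline vertices, projects cells segment-wise, and stops
  when mean displacement falls below 1e-4 of the data scale (at most 50
  iterations; non-convergence returns the last iterate with a warning).
  Pseudotime is arc length normalized to [0, 1], oriented so adult
  training cells average higher than the youngest.
* The pseudobulk tests delegate the linear-model machinery to
  limma/edgeR (voom weights for the multi-age F-test, intensity-trend
  empirical Bayes for two-group contrasts); BH adjustment validates its
  input and delegates to `p.adjust`.
* The inter/intra distance t-test treats sample pairs as independent
  observations, exactly as the source analyses do. The dependence among
  pairwise distances makes the test approximate; the acceptance suite
  verifies its calibration empirically (median null effect size within
  [0.9, 1.1], type-I rate within [0.01, 0.12] at alpha = 0.05) rather
  than assuming it.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` size their simulations so the
full set of checks completes comfortably on a single CPU: 30 cell types
at 300 cells per age for class recovery; 200 permuted-null and 20
planted-shift replicates for contrast calibration; 50 null simulations
for FDR calibration; 10–20 seeded runs of the one-stage-delay recovery
with 9 cell types (three per maturation class) each. These sizes are the package's validation
conditions; all thresholds they are held to (90% class recovery, 80%
shift detection, 1.5x nominal FDR, and so on) are stated in the tests
themselves.

# Known limitations

* The label-transfer prediction score is a k-NN soft vote, a deliberate
  methodological substitution for anchor-based canonical-correlation
  transfer; only the threshold-rule semantics are claimed to match, not
  score equivalence.
* Distance trajectories carry an additive centroid-noise floor at every
  pre-adult age (the adult is its own reference, so its distance is
  exactly zero). The floor shrinks with cell count; analyses comparing
  distances across cell types should keep per-age cell counts comparable.
* The delay estimator searches integer stage shifts only.
* Pseudotime assumes a single unbranched maturation lineage per cell
  type; branching topologies are out of scope.
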