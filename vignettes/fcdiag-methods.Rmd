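---
title: "Connectivity networks, graph features, and stratified diagnosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity networks, graph features, and stratified diagnosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdiag)
```

## The problem

`fcdiag` implements a complete analysis pipeline for diagnosing a clinical
condition (the motivating case is ADHD versus typically developing
controls) from three kinds of per-subject information:

1. **resting-state functional connectivity**, summarised as a weighted
   116-node graph over atlas regions built from ROI-averaged BOLD time
   series;
2. **anatomical morphometry**: vertex-wise cortical thickness resampled
   onto a subdivided-icosahedron grid, per-region statistics, and
   ICV-normalised structure volumes;
3. **phenotypes**: age, gender, handedness, Verbal/Performance IQ (with
   missingness), and acquisition site.

A stratified linear-SVM framework ranks features, selects the top *K*,
and reports ROC/AUC with permutation-based significance. Because the
multi-site clinical data the design targets cannot ship with a package,
a first-class synthetic cohort generator reproduces the statistical
structure that every stage assumes, with planted ground truth, so the
entire pipeline is testable end to end.

## Network construction

Three estimators turn a `roi_timeseries` (band-passed to 0.009–0.08 Hz
with a zero-phase order-2 Butterworth filter; repeated sessions
concatenated) into a `weighted_network`:

* **Corr** — pairwise Pearson correlation, Fisher-transformed to
  two-sided p-values with an effective sample size
  `T_eff = T / (1 + 2 Σ_k ρ_x(k) ρ_y(k))` (Bartlett correction, lags up
  to `min(T/4, 50)`, floored at 4) to account for the autocorrelation the
  band-pass introduces; Benjamini–Hochberg thresholding at q = 0.01;
  surviving edges weighted `|r|`.
* **SIC** — sparse inverse covariance: block coordinate-descent
  graphical lasso (off-diagonal L1 penalty, default λ = 0.1) on the
  correlation matrix; edge weight = partial-correlation magnitude
  `|−Θ_ij/√(Θ_ii Θ_jj)|`, which is scale-free and lies in [0, 1]. Entries
  below 1e−8 are snapped to zero so sparsity is unambiguous. The solver
  stops when the working covariance changes by less than 1e−4 (relative)
  or errors after 500 sweeps.
* **Kappa** — Patel's κ extended to continuous signals by min–max
  rescaling each series to [0, 1]; no edge threshold.

Affinity weights are magnitudes (the sign is kept as metadata); the
distance view is the reciprocal `w_distance = 1/w_affinity`, with absent
edges at infinite distance — the resistance/conductance duality of an
electrical circuit. Every graph measure declares which mode it consumes
and errors on the wrong one rather than silently miscomputing.

## The graph-feature battery

Per network the package emits a stable, named feature vector:

* shortest-path statistics (average/harmonic path length, diameter,
  radius, eccentricities, global efficiency) on distance weights,
  restricted to finite pairs with an `is_connected` flag when the graph
  is disconnected;
* binarised clustering coefficients (any positive weight is an edge);
* weighted degrees, degree entropy (natural log over the L1-normalised
  degrees), assortativity (Pearson correlation of endpoint degrees over
  both edge orientations; regular graphs get 0 plus a degenerate flag);
* betweenness with fractional credit across tied geodesics, normalised
  by `(n−1)(n−2)/2`; per-node dominance `b'_max − b'_i` and Freeman's
  central point dominance `Σ(b'_max − b'_i)/(n−1)`;
* effective-resistance eccentricities, radius, diameter, and the
  Kirchhoff index from the Laplacian pseudoinverse (per component when
  disconnected);
* spectral separability: 2nd and 3rd smallest eigenvalues of `L = D − W`
  and of the normalised Laplacian (computed through the symmetric form
  `D^{−1/2} L D^{−1/2}`, which shares its spectrum);
* isoperimetric estimates: sweep cuts over the Fiedler vectors of both
  Laplacians and over the grounded potential `L₀x = d` (ground = highest
  degree node), evaluating every prefix subset under both the size- and
  volume-normalised ratios; the exact problem is NP-hard, so these are
  upper bounds that the test suite verifies against exhaustive search on
  small graphs (equality on symmetric fixtures);
* minimum cycle basis (Horton candidates, greedy GF(2) selection by
  ascending weight): dimension, percent non-triangle cycles, mean/max
  non-triangle weighted length, total basis length. Shortest-path ties
  would make Horton's candidate set fragile, so path computation uses a
  deterministic multiplicative jitter of 1e−12 per edge index; reported
  weights use true distances. The mean/max lengths are over non-triangle
  cycles only (triangle lengths are redundant with the triangle count),
  while the total is over the whole basis;
* symbolic-elimination fill-in under four orderings — lexicographic,
  greedy minimum degree, reverse Cuthill–McKee (minimum-degree start,
  ties by index), and a Dulmage–Mendelsohn-style permutation — crossed
  with affinity thresholds {0, 0.1, 0.3, 0.5, 0.7, 0.9} plus the
  surviving edge count: 30 features. Because the Laplacian pattern has a
  full structural diagonal, the bipartite DM decomposition's row
  permutation reduces to grouping nodes by connected component; that is
  the reading implemented. Fill-in is counted by the elimination game on
  the graph structure, which equals the symbolic Cholesky fill of the
  permuted matrix while sidestepping the Laplacian's singularity;
* all `n(n−1)/2` edge weights as individual features (6,670 at n = 116).

All tie-breaking (equal-length paths, equal sweep ratios, equal cycle
weights, ordering ties) resolves by canonical node index, so feature
vectors are platform-stable. Fill-in features are intentionally
label-order-dependent (the lexicographic ordering is the reference the
others are compared against); every other global feature is invariant
under node relabelling, and the test suite checks exactly that split.

## Anatomical features

`make_icosphere(level)` subdivides a regular icosahedron with midpoint
deduplication (`10·4^level + 2` vertices; level 4 gives the 2,562-vertex
hemisphere grid, hence 5,124 thickness features per subject). Structure
volumes, including gray/white hypointensity volumes, are divided by the
subject's intracranial volume to control for head size and age;
thickness and curvature statistics are left unscaled; vertex curvature
maps are not part of the schema. Constant features are excluded
cohort-wide during table assembly, never per subject, so a subject with
a flat thickness map survives assembly.

## The classification framework

`assemble_feature_table` z-normalises imaging features, drops constant
columns, imputes missing IQ with the cohort mean and adds the binary
`NoIQ` flag plus one-hot site indicators. Two normalisation scopes
exist: the default computes means/SDs and imputation values on the
training partition only (no information from test subjects touches
training), while `normalization = "global"` reproduces the classical
whole-dataset convention. Both are useful: one for methodological
soundness, one for comparability with analyses that normalised over
everyone.

Folds are deterministic: subjects sort lexicographically by (site,
label, gender, age, id) and deal round-robin, which bounds the per-fold
imbalance of every contiguous sort cell at one subject. Stratification
fits separate classifiers per gender (or per gender × training-age
quartile bins, six strata) and pools decision values across strata
before any ROC is computed, treating the pooled outputs as one
classifier.

Three rankings are computed inside each training fold: two-sample
pooled-variance t; single-feature nested-CV accuracy (inner folds built
by the same deterministic rule, default 2); and SVM-RFE, which halves
the surviving features by weight magnitude until ten or fewer remain and
scores by (survival round, then weight). Fold rankings are averaged by
mean rank for the final model. The classifier is a linear SVM at fixed
cost 1 (hinge loss, no class weighting, no scaling); its decision
function is canonicalised so positive scores always mean the positive
diagnosis regardless of row order. AUC uses the Mann–Whitney midrank
convention; accuracy reports the best point on the ROC, with the
threshold chosen on training scores by default (a `same_set` option
exists because the original convention is ambiguous). Feature impact is
weight × within-class mean. The permutation test shuffles training
labels within each (stratum, fold) cell — preserving fold balance and
the stratification — and reruns selection, training, and evaluation;
it reports the mean, the SD of the estimate of the mean, and the SD of
the permutation distribution itself.

## What the synthetic cohorts emulate

Per-subject signals are i.i.d. Gaussian draws with covariance equal to
the inverse of a group-specific sparse precision, then band-passed.
This is the simplest model with an exact target covariance; the filter
then induces the temporal autocorrelation that exercises the effective
sample-size correction (band-passing 0.009–0.08 Hz at TR 2 s leaves
roughly 28% of the nominal samples effective). The baseline precision
is a ring (partial correlation 0.35) plus random chords (0.25), chosen
once so that implied marginal correlations (~0.4 between connected
regions) give corr networks with realistic density (~20–30% of edges
survive FDR at q = 0.01 and T = 250); the diagonal is inflated until
the smallest eigenvalue is at least `(0.05 + effect_magnitude)` times
the diagonal value, and the planted entries are injected at
partial-correlation scale (`−mag·√(θ_ii θ_jj)` on node-disjoint pairs,
so the planted partial correlation equals the configured magnitude
exactly and the perturbation provably keeps both precisions positive
definite). The default effect magnitude of 0.15 reflects the size of
group differences plausible against a strong baseline; much larger
planted effects would force a weaker (unrealistically sparse) baseline
through the positive-definiteness constraint.

Phenotypes: ages uniform on 7–21 years, eight sites, ~53% male at the
default sizes, gender-specific ADHD prevalence (defaults 0.45/0.25,
≈36% overall), Combined/Inattentive/Hyperactive subtype split
(0.5/0.45/0.05 — Hyperactive deliberately rare), IQ Gaussian with SD 15
shifted down by 9 points under ADHD, both IQs jointly missing at rate
0.1. Site effects are additive offsets on anatomical means and
multiplicative gains on signal amplitude — the minimal mechanism that
makes site indicators informative. `female_effect_scale` scales the
planted edge and thickness effects in girls, creating the
gender-dependent structure that makes stratification matter. One
caveat the test suite documents: a *sign-flipped* network effect is
invisible downstream because affinity weights are magnitudes, so
gender-dependent network effects should differ in size, not sign;
thickness effects enter linearly and may flip.

What the generator does **not** emulate: head motion, hemodynamic
response, scanner-specific autocorrelation structure, spatial
correlation between neighbouring thickness vertices, non-Gaussian
heavy tails, or site-by-diagnosis confounding. Passing tests therefore
demonstrate the pipeline's correctness and calibration under its own
assumptions, not clinical performance on real data.

## Numerical choices and degenerate inputs

* Graphical lasso: relative tolerance 1e−4 on the working covariance,
  500 sweeps maximum, coordinate-descent inner loop at 1e−6; weights
  under 1e−8 snapped to zero. The solver is validated against an
  independent reference solution and a KKT stationarity check.
* Effective sample size clipped to [4, T] so `√(T_eff − 3)` is defined.
* Constant regions are isolated with a warning (corr, kappa) or error
  (SIC, which cannot standardise them).
* Disconnected graphs: path and resistance statistics over finite pairs
  with a flag; Fiedler values and isoperimetric numbers 0 by definition;
  zero-degree entropy defined as 0 with a warning.
* Pairs with κ denominator 0 get κ = 0; assortativity on regular graphs
  returns 0 with a degenerate flag.
* Any failing feature block inside `extract_all_features` falls back to
  its documented degenerate default rather than dropping names, so every
  network of the same size yields the same feature schema.

## Calibration experiments and problem sizes

The acceptance script and suite run, at sizes chosen to keep the whole
analysis on a laptop-class single core:

* corr false-edge rate on independent 10-region data (T = 500, 100
  replicates): observed ≈ 0.001 against the q = 0.01 target;
* SIC support recovery at λ = 0.1 with five planted conditionally
  independent pairs (partial correlation 0.4) and 2,000 i.i.d. samples:
  the i.i.d. design isolates the estimator from the band-pass (which
  would cut the effective sample size ~4×) and from indirect
  correlations (a ring baseline induces two-hop marginal correlations
  ≈ 0.12 > λ, which the lasso legitimately fits as small extra edges);
* a 300-subject planted-effect cohort (16 regions, T = 250, icosphere
  level 1, six effect edges at 0.35, thirty thickness vertices at
  0.25 mm, IQ shift 9, female effects scaled 0.6) classified with
  gender stratification at K = 50 — held-out AUC well above 0.85 — and
  a matched zero-effect cohort whose held-out AUC falls inside the
  100-permutation null band (chance ± 3 permutation SDs);
* oracle equivalence on 200 random weighted graphs of 4–6 nodes against
  brute-force path, betweenness, resistance, cycle-basis, fill-in, and
  exhaustive isoperimetric computations;
* leakage: flipping every test label changes no trained model bit;
  identical configuration and seed reproduce result files byte for
  byte.

## Known limitations

* The isoperimetric values are estimates (sweep cuts); they are exact on
  the symmetric fixtures tested but only upper bounds in general.
* The greedy minimum-degree ordering is exact minimum degree, not the
  approximate-minimum-degree heuristic of large sparse solvers; at 116
  nodes the distinction is irrelevant.
* `rank_nested_cv` trains one SVM per feature per inner fold and is the
  slowest ranking method by a wide margin; the default experiment runs
  it only when requested.
* Kappa's continuous extension depends on the min–max rescaling; signals
  with heavy tails compress most of the range, which mirrors the known
  sensitivity of the original binary measure to thresholding.
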