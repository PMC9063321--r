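---
title: "Evolving connectivity motifs: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving connectivity motifs: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Dynamic functional network connectivity (dFNC) summarizes a resting-state
fMRI scan as a trajectory through connectivity space: at each sliding-window
position, the pairwise Pearson correlations between `N` network timecourses
form one `D = N(N-1)/2`-dimensional frame. The dominant analysis tradition
clusters these frames into a handful of time-blind "snapshot" states and
models the dynamics as transitions between them. That discards how
connectivity *evolves* — the multi-window paths through which the brain
enters and leaves characteristic configurations.

`evodfnc` implements an alternative: extract a small set of **multiframe
evolving motifs** (each `tau` frames by `D` features, a short "movie" of
connectivity) directly from the data, then score every subject's observed
dynamics against them. The stages are:

1. **Windowed connectivity** (`compute_windowed_dfnc()`): tapered sliding
   window, step 1 TR; plus the conventional time-blind k-means baseline
   (`cluster_snapshots()`, 5 states) for comparison.
2. **Planar embedding** (`embed_dfnc()`): all subjects' frames are embedded
   jointly into 2D with UMAP, repeated `R` times and averaged pointwise. The
   UMAP parameters are chosen so each subject's trajectory embeds as a
   continuous curve (`continuity_ratio()` is the diagnostic).
3. **Linear trajectory exemplars** (`exemplars_from_embedding()`): every
   length-`tau` sub-segment of every embedded trajectory is linearized to a
   (midpoint, slope, length) summary; k-means on the (midpoint, slope)
   triples yields `K` exemplars — dominant local directional trends of the
   group-level dynamics.
4. **Lifting** (`lift_all()`): each exemplar is divided into `tau` evenly
   spaced points and each point is mapped back to connectivity space as the
   mean of the `n` dFNC frames whose embedded coordinates are nearest — a
   data-driven inverse of the (non-invertible) embedding. The lifted
   sequences are the evolving motifs.
5. **Representation** (`ri_series()`, `cluster_weight_vectors()`): each
   observed length-`tau` window is expressed as a weight vector over the `K`
   motifs (representational importance, RI); weight vectors are clustered
   into `M` meta-states whose centroid-weighted motif sums give meta-motifs,
   with per-subject occupancy rates.
6. **Statistics** (`fit_group_model()`, `fit_symptom_model()`): per-feature
   OLS with diagnosis, age, gender and head motion; a patients-only model
   with six positive-symptom scores entered jointly; BH-FDR (default) or
   Bonferroni correction.

## Parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| `window_len` | 22 | TRs | sliding-window length (44 s at TR = 2 s) |
| `sigma` | 3 | TRs | Gaussian taper width; `Inf` = pure rectangle |
| `tau` | 44 | windows | motif duration, twice the window length |
| `n_neighbors` | 25 | frames | UMAP neighborhood size |
| `min_dist` | 0.75 | – | UMAP minimum embedded distance |
| `n_runs` | 25 | – | embedding runs averaged |
| `k` | 10 | – | linear trajectory exemplars / motifs |
| `n_lift` | 25 | frames | neighbors averaged per lifted point |
| `m` | 10 | – | meta-state clusters |
| `snap_k` | 5 | – | time-blind snapshot states |
| `iter_max`, `restarts` | 2000, 250 | – | k-means control (500 restarts for weight vectors) |

The taper is a rectangle convolved with a Gaussian, truncated and
renormalized; the taper weights enter the correlations as observation
weights in the means, variances and covariances. A Fisher z-transform of the
correlations is available (`fisher_z = TRUE`) but off by default. The window
count follows the inclusive convention `W = T - window_len + 1` (step 1),
and the RI series likewise has `W - tau + 1` rows; both conventions are
asserted in the test suite.

## Numerical choices and conventions

* **Segment linearization** uses the ordinary least-squares slope of y on x,
  not total least squares: near-vertical segments produce arbitrarily large
  OLS slopes, which is exactly what the slope bound — the largest coordinate
  magnitude in the embedding, `max(|x|, |y|)` — is there to clip. A segment
  with constant x takes `+bound` by convention. Clipping happens before
  clustering so the bound is part of the clustering inputs.
* **"Midpoint"** of a segment is the centroid of its points; for straight,
  uniformly sampled segments this coincides with the chord midpoint, and it
  stays well defined for curved ones. Segment **length** is the maximum
  pairwise distance among the points.
* **Exemplar orientation**: a line segment has no intrinsic time arrow. We
  orient each exemplar by the sign of the dot product between its direction
  vector and the mean temporal displacement (last minus first point) of its
  member segments; a zero dot product maps to +1.
* **k-means** uses k-means++ seeding, a fixed number of restarts with the
  best inertia kept, Lloyd iterations delegated to `stats::kmeans`, and
  empty clusters reseeded from the point farthest from its centroid. The
  whole procedure is bit-reproducible for a fixed seed.
* **Nearest neighbors in lifting** are found by exact distance sort;
  distance ties at the n-th neighbor break toward the lower frame index.
  Neighbors are drawn from all subjects jointly, and only spatial position
  is used — slope information plays no role in the inversion, because the
  embedding itself is purely spatial.
* **Argmax RI ties** break toward the smallest motif id. Zero-variance
  frames (flat connectivity, possible in synthetic data) get correlation 0
  with a classed warning instead of an error.
* **Zero-variance responses** in the regression models get coefficient 0 and
  p = 1 by convention; rank-deficient designs abort with the collinear
  columns named.

## Averaging embedding runs: the one deliberate deviation

UMAP is stochastic, so the embedding is stabilized by averaging `R`
independent runs pointwise. A literal pointwise average, however, treats the
runs as if they shared a coordinate frame — but each run is defined only up
to rotation, reflection and scale. At the problem sizes we validate on, the
literal average of 25 runs shrinks the embedding by roughly an order of
magnitude and erases the group-level trajectory geometry the exemplar stage
depends on: in our planted-motif experiments one of two motifs became
unrecoverable (best frame-wise correlation 0.56 versus the 0.7 recovery
bar), while mapping runs 2..R onto run 1 with the closed-form orthogonal
Procrustes similarity transform before averaging preserved the geometry
(both motifs ≥ 0.74) and improved the continuity diagnostic. `evodfnc`
therefore aligns runs by default (`align_runs = TRUE`); the literal
unaligned average remains available and is what the unit tests check against
the hand-coded averaging formula.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` builds cohorts in which every pipeline claim can be
checked against known ground truth:

* **Anchors**: block-modular correlation matrices (3 modules; within-module
  correlation +0.6, selected between-module blocks -0.3, ridge-adjusted to
  positive definiteness) emulate modular whole-brain connectivity patterns;
  a low-contrast (0.15) anchor plays the role of weakly structured rest.
* **Evolving motifs**: linear morphs between two anchors over 65 TRs — with
  a 22-TR window that is exactly `tau = 44` windows, so a planted motif and
  a lifted motif are compared like with like. Ground truth is stored at
  window resolution: the per-TR target matrices convolved with the analysis
  taper and renormalized, because windowing is a smoothing the pipeline
  cannot undo.
* **Dynamics**: each scan holds two motif slots (start and end) separated by
  rest; group 1 draws motif 1 per slot with twice the group-0 probability
  (2/3 vs 1/3 by default). Timecourses are sampled as
  `x_t = chol(C_t)' z_t + noise` with i.i.d. standard normal `z_t` and white
  measurement noise (sd 0.1).
* **Covariates**: age, gender and mean frame displacement from realistic
  marginals, with optional logit effects on motif usage (zero by default);
  patients get six integer symptom scores.

Deliberately *not* emulated: hemodynamic filtering and autocorrelated fMRI
noise spectra, site and scanner effects, subject-specific network
decompositions, and motion artifacts. Passing the recovery tests therefore
shows that the implementation faithfully executes the method and that the
method can recover planted evolving structure at realistic contrast and
noise — not that it will do so in real data, where neighborhood structure in
connectivity space is noisier and the "true" motifs are unknown.

## Problem sizes used for validation

The test suite and `scripts/acceptance.R` validate on a 12-network tiny
scale rather than the 47-network full scale (the feature dimension drops
from 1081 to 66; the dimensional identities for `N = 47` are still computed
and asserted directly). The standing conditions are:

* **Continuity and motif recovery**: 20 subjects (10 + 10), 158 TRs, two
  planted motifs, full reference parameters including 25 averaged embedding
  runs. The suite asserts mean within-subject `continuity_ratio()` < 0.5 and
  at least one lifted motif per planted motif with mean frame-wise Pearson
  correlation ≥ 0.7.
* **Group-effect recovery**: ten independent replicate cohorts of 30 + 30
  subjects with the planted 2:1 usage ratio — the size a small case-control
  study would target (20 subjects total gives roughly coin-flip power for
  this effect, which no analyst would design for). Each replicate uses 3
  embedding runs and 50 k-means restarts so ten full pipelines stay
  tractable; the suite asserts a positive diagnosis effect at p < 0.05 on
  the subject-mean RI of the best-recovered motif in at least 8 of 10.
* **Null calibration**: 200 patient-only cohorts (n = 50) with features
  independent of symptoms; the per-symptom type-I error at α = 0.05 must
  fall in [0.02, 0.09].

## Known limitations

* The method has many coupled parameters (window, `tau`, UMAP neighborhood,
  `K`, `M`); the defaults here follow the reference analysis and the elbow
  criterion behind `K = M = 10` is exposed only as an inertia-versus-k table
  (`exemplar_inertia_table()`), not automated.
* Lifting assumes locally uniform traversal speed along an exemplar: `tau`
  evenly spaced 2D points stand in for `tau` evenly spaced time points,
  which distorts timing where the embedding compresses a path.
* Exemplars are straight lines; strongly curved group-level flows are
  approximated piecewise by multiple exemplars, splitting their
  representational importance.
* With few subjects, cross-subject neighborhoods in connectivity space are
  sparse, and windowed-correlation estimation noise (22 TRs per window) sets
  a floor on how sharply the embedding can align repeated traversals of the
  same underlying motif.
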