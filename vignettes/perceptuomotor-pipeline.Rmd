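---
title: "Perceptuomotor gaze analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptuomotor gaze analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(knapgaze)
```

This vignette is the package's own account of the science it implements:
the measurement models, the assumptions behind them, the parameters that
matter, and the places where the design was genuinely open and a choice had
to be made.

## The study design being modelled

Novice participants watch the same ~17-minute demonstration of an expert
stone knapper shaping a handaxe, once before training and again after each
of two 50-hour practice blocks (`Pre`, `Post1`, `Post2`). While watching,
they press a key at moments that feel meaningful; their gaze is sampled at
60 Hz in normalized screen coordinates; at each assessment their motor
skill is scored (handaxe score, percussion error). Every second of the
video carries one of six action-phase labels: core reposition, core move,
light percussion, percussion, grinding, tool change. Core moves — the
demonstrator repositioning the parent stone — turn out to be the moments
viewers flag as meaningful, and they are where the gaze analysis
concentrates.

## Salience: from key presses to analysis windows

Press latencies are rounded to the nearest second (half-up; a latency of
exactly 0.5 s lands in second 1) into a binary subject × second matrix.
A 10-s window advanced in 5-s steps yields a probability series: the
fraction of subjects with at least one press in the window (a subject
counts once, however often they pressed). Windows at or above the 90th
percentile of this series whose dominant phase is the target phase are
retained.

Open points the package had to settle:

* **Threshold pooling.** The probability series is pooled across the three
  sessions (rows are subject-session pairs), because a single set of
  windows is used at every assessment. A per-session mode would be a
  one-line change but is not the default.
* **Percentile definition.** Type-7 (linear interpolation between order
  statistics), R's default.
* **Dominant phase.** Strict majority of the window's seconds; ties break
  toward the phase occurring earliest in the window.
* **Overlap.** Overlapping retained windows merge into maximal runs so no
  gaze sample is counted twice; the unmerged windows are kept alongside
  for bookkeeping. Trailing partial windows are dropped.
* **Window cap.** `run_config(n_windows = 40)` keeps at most the 40
  highest-probability merged runs (earlier runs first on ties), the
  bookkeeping used throughout: 40 windows × 11 subjects × 3 sessions =
  1,320 rows per gaze parameter.

## Temporal dispersion: CV and Ward time clusters

The gaze coefficient of variation over a window's continuous x-gaze,
`sd(x)/mean(x)`, is the scale-free dispersion summary. Only the x
coordinate enters the statistics (the working edge is a vertical feature);
y is generated and carried but unused.

The window's time × subject matrix (rows = 60-Hz time samples, columns =
subjects, entries = x-gaze; invalid samples linearly interpolated,
subjects more than half-invalid excluded) is clustered with Ward's
minimum-variance criterion on Euclidean distances **over time rows**, so
the output is *time clusters*: stretches of the window where the group's
gaze configuration is internally similar. Clustering subjects instead
would not produce the time centroids the spatial stage needs.

`ward_cluster()` delegates the agglomeration itself to
`stats::hclust(method = "ward.D2")`; the test suite verifies its merge
heights against an independent Lance-Williams recursion. Derived outputs
are computed here: the within/between-class percentage decomposition of
the total sum of squares (they partition it exactly), the mean pairwise
distance between cluster centroids (the "dissimilarity" summary — the
package's reading of an otherwise underspecified statistic, flagged as an
interpretation), and per-cluster central objects: the *observed* row
closest to the cluster mean, ties broken toward the earliest timestamp.
The central object's timestamp is the cluster's time centroid and its
per-subject entries feed the edge-distance computation.

### Choosing the number of clusters

With `k = NULL` the cut is chosen automatically within `k_range = 2:5`:

* the candidate maximizing the **ratio** of successive merge heights wins.
  Ward heights grow mechanically with cluster size, so absolute gaps are
  biased toward k = 2; the relative gap is scale-aware.
* **Despiking first.** Brief off-task excursions (a glance at the
  demonstrator's hands, a saccade in flight) are value outliers that Ward
  isolates in its very top merges, which masks the sustained regime
  structure from any truncation rule and — worse — lets an excursion
  become a cluster whose central object is an excursion sample. Before
  truncation, samples deviating from their subject's ~1-s running median
  by more than 6 robust SDs (MAD of the residual, floored at 0.05
  normalized units) are set aside; the tree is rebuilt and cut on the
  remaining rows; the spikes are then reattached to the nearest centroid.
  Reattached rows are far from their cluster mean by construction, so they
  never become central objects. An explicit `k` bypasses despiking.

On windows spanning about three core rest positions this recovers k = 3 in
well over 80% of cases, matching the typical three-cluster structure of
real core-move windows.

## Spatial dispersion: RANSAC edge tracking

Frames carry feature-point clouds (the pipeline starts downstream of any
image processing). Registration of the core template onto a frame is by
RANSAC: a translation hypothesis from one random template-point /
frame-point pairing; consensus = frame points within `inlier_tol` of a
translated template point (nearest neighbour); least-squares refit on the
winning consensus set; adaptive early stopping at 99.9% confidence.
Defaults — 500 iterations, tolerance 0.005 normalized units, quality floor
0.3 on the inlier fraction — are conventional choices at the scale of a
1680 × 1050 frame. The model family is translation-only: between
neighbouring frames a rigid core shifts but does not visibly rescale, and
the working edge is a translation-equivariant feature (the registered
bounding box's x-maximum). Tracking warm-starts each frame at the previous
estimate and accepts it without sampling when it already explains half the
frame points; low-quality frames get `edge_x` interpolated from their
neighbours, and a fully failed sequence is returned flagged rather than
guessed.

Signed distance is `gaze_x − edge_x` (positive = right of the edge),
evaluated at the nearest tracked frame to each time centroid (≤ 16.7 ms
discrepancy at 60 Hz vs 30 fps — negligible). Per subject and window, the
mean signed distance and the sample SD across the window's centroids
("edge variability") are reported; the SD is shift-invariant, so the
signed-vs-absolute question only affects the mean.

## Robust change statistics

* **Harrell-Davis deciles.** `q`-th quantile as the beta-weighted sum of
  all order statistics, `w_i = I(i/n; a, b) − I((i−1)/n; a, b)` with
  `a = (n+1)q`, `b = (n+1)(1−q)`. Weights sum to one; estimates are
  monotone in `q`.
* **Shift functions.** Decile differences (second sample minus first) with
  percentile-bootstrap CIs from `n_boot = 2000` independent resamples of
  each group, and per-decile p-values `2·min(P(d* < 0), P(d* > 0))` (ties
  split evenly) adjusted across the nine deciles by Hochberg's step-up
  (`stats::p.adjust`). The bootstrap p-value construction is the package's
  choice; the pieces it connects (percentile bootstrap, Hochberg) are
  fixed. Sessions are compared as independent groups (`Shift1` = Post1 vs
  Pre, `Shift2` = Post2 vs Post1); under the null the family-wise error of
  the adjusted shift function calibrates to ≈ 5% (checked by simulation at
  n = 50 per group).
* **Effect sizes.** Hedges g (pooled-SD mean difference times
  `1 − 3/(4·df − 1)`, appropriate below n ≈ 20), eta² = SS_between /
  SS_total (sums of squares from `aov`; for a single factor this equals
  the type-II value), and rank epsilon² = `H/((n²−1)/(n+1))` with H from
  `kruskal.test`.
* **Learning slope.** OLS of a participant's handaxe scores on the square
  root of cumulative practice hours; with training converging everyone to
  a similar level, a flatter slope mostly reflects higher initial
  aptitude.
* **Permutation.** Before averaging windows into subject-session means,
  subject identifiers are shuffled independently within each session.
  Session-level distributions are unchanged; the relabelling breaks any
  incidental subject-window alignment.

## Canonical correlation

Both variates are z-scored (denominator n − 1 throughout); covariance
blocks are whitened by their Cholesky factors and the SVD of
`La⁻¹ Σab Lb⁻ᵀ` gives weights, variates and canonical correlations, which
are verified internally (to 1e-8) against the Pearson correlations of the
paired variates. All `min(p, q) = 3` modes are reported. Weights are
sign-indeterminate, so the first nonzero element of each performance-side
weight vector is made positive, flipping the paired gaze-side column with
it. With the study's n ≈ 11 subjects and three variables per side the
estimates are high-variance; the function warns below `n < 5·max(p, q)`
but computes, matching how such data are analysed in practice.

## The synthetic experiment generator

`synth_config()` / `generate_dataset()` produce a complete experiment as a
pure function of the configuration (seed included): phase track, press
logs, gaze streams, working-edge trajectory, per-frame feature points,
performance table, and the latent per-subject factors that tie them
together.

What it emulates, and how:

* **Phase track.** Segments drawn phase-by-phase (weights, shifted-Poisson
  lengths), or an explicit deterministic layout.
* **Presses.** Locked to salient-phase onsets with per-subject Bernoulli
  participation (`press_response_prob = 0.8`), a truncated-normal reaction
  lag (1.0 ± 0.5 s), and a small Poisson false-alarm background.
* **Working edge.** A piecewise-constant step process — the core sits at a
  rest position until repositioned, roughly every 5 s — plus a millimetric
  sinusoidal wobble. Steps, not smooth drift, are what a repositioned core
  actually does; they give windows their time-cluster structure; and, being
  common to gaze and edge, they cancel exactly out of edge-referenced
  distances. `edge_level_values` plants a deterministic level cycle when a
  known number of well-separated regimes per window is wanted.
* **Gaze.** An alternating renewal process: edge-locked fixations (Gamma
  durations, 0.5-s mean) anchored at the edge plus a per-fixation offset
  (mean −0.10: on the core body, left of its right-most edge; SD per
  session from `edge_offset_sd_by_session`), optionally followed by one
  brief exploratory glance (≤ 0.3 s, anchored around x = 0.15 — the
  demonstrator's hands and debris, well off the core). Saccades are
  instantaneous; Gaussian jitter (SD 0.01) rides on every sample. Two
  session-dependent behaviours distinguish novices: the glance rate and a
  small exponential re-foveation lag after each core reposition.
* **Performance.** Handaxe scores rise along a saturating power curve in
  √hours (`2 + 7·(1 − e^{−0.25·√h})`), percussion error decays stepwise
  (×0.55 per session); additive Gaussian noise on both (the error model is
  the package's choice). A latent aptitude shifts both curves and is
  correlated (`latent_coupling = 0.8`) with the subject's gaze-offset
  factor — the structure the CCA stage is meant to find.

### Calibration and the planted session profiles

The defaults *are* the study conditions the package tests itself against:
`gaze_cv_by_session = (0.20, 0.11, 0.14)` (dispersion drops after the
first practice block) and `edge_offset_sd_by_session = (0.02, 0.02, 0.06)`
(edge-referenced spread jumps at the final assessment). The glance time
fraction is moment-matched per session so the overall x-variance hits the
CV target given what the edge steps, offsets, jitter and lag already
supply. Two caveats are worth knowing: the matching is on global variance,
while the pipeline measures CV per window and averages, so realized CVs
sit somewhat below their targets (Jensen's inequality, plus windows
spanning fewer edge levels than the long run); and central-object
selection shrinks the measured edge variability to roughly half the
per-fixation offset SD (the selected row is jointly close to all subjects'
cluster means). The default targets are set far enough apart that the
planted *orderings* survive both effects; recovering those orderings in
at least 90% of seeded end-to-end runs is part of the test suite.

What the generator does **not** model: pixel-level video, pupils or
eyelids, blinks (an optional missingness flag exists, but no blink
structure), smooth pursuit, vertical task structure, or tracker noise that
correlates across subjects. Passing tests therefore say the *pipeline*
recovers what was planted — not that real gaze obeys this generative
model.

## Problem sizes used by the test suite

Unit tests run on seconds-long synthetic videos. The end-to-end recovery
checks use a 512-s video with up to 12 windows and 200 bootstrap
resamples, twenty seeded runs; the bookkeeping check uses the full 1024-s
layout with 40 planted core-move segments; null-calibration and coverage
simulations use 500 replicates at n = 50–100 per group with 2000
bootstrap resamples. These sizes were chosen to exercise every code path
at stable statistical resolution while keeping a full suite run in the
minutes range.

## Known limitations

* The dissimilarity summary is one defensible reading (mean pairwise
  centroid distance) of a loosely specified statistic.
* Edge tracking is translation-only; cores that visibly rotate or rescale
  between frames would need the model family extended.
* Shift functions treat sessions as independent groups; a paired variant
  would be natural for within-subject designs but is not the default.
* With 11 subjects, CCA point estimates (and the leading r² in
  particular) are optimistic; they are reported for comparability, not as
  unbiased effect estimates.
* The missingness flag is Bernoulli; structured gaps (blinks, tracker
  dropouts) are not modelled.
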