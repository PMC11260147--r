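---
title: "Methods: hurdle forecasting of fishing effort under MPA expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hurdle forecasting of fishing effort under MPA expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(effortcast)
```

## The estimand and the model

The package predicts annual fishing hours per grid pixel and, from those
predictions, the *difference* between a world with an expanded no-take
MPA network and a business-as-usual (BAU) world that keeps only the
existing network. Effort is zero-inflated (many pixels see no fishing in
a year) and heavily right-skewed, which motivates a two-part hurdle
structure fitted independently per forecast horizon $t \in \{1,2,3\}$
years:

* **Stage 1 (extensive margin).** A classifier emits $p$, the
  probability that any fishing occurs in a pixel-year. Predictions are
  thresholded at $\tau$, chosen to maximise the cross-validated F1 score
  rather than fixed at 0.5 — with imbalanced occurrence the F1-optimal
  cutoff is materially different, and the composed hurdle uses this tuned
  $\tau$ throughout (the plain-0.5 alternative is a one-line change in
  `predict_hours()` but is deliberately not the default).
* **Stage 2 (intensive margin).** A regressor predicts
  $\log(h/m^2)$ — effort normalised by the spherical pixel area so that
  latitude-dependent pixel sizes do not masquerade as effort gradients —
  using only the positive observations. Natural log throughout.
* **Retransformation.** Predictions return to the level scale with
  Duan's nonparametric smearing estimator
  $S = \operatorname{mean}(\exp(\varepsilon))$ over the fitting
  partition's log-scale residuals. $S$ corrects the downward bias of
  $\exp(\hat y)$ under non-normal residuals; it is refit inside each
  cross-validation fold (on the fold's analysis split) so that fold
  metrics are honest, and finally on the whole fitting partition.

The composition is exact and row-wise:
$\text{hours} = \mathbf{1}\{p \ge \tau\} \cdot S \cdot \exp(\hat y) \cdot
\text{area}$. The test suite asserts this identity on every prediction
batch.

Both stages default to 500-tree random forests (`ranger`), tuned over a
seeded maximin Latin-hypercube grid of 10 (mtry, min-node-size)
combinations — a space-filling realisation of an "entropy-maximising"
design. Stage 1 tuning maximises mean-across-folds ROC AUC; stage 2
maximises mean-across-folds `rsq_trad` computed on *level* predictions
after per-fold smearing. Ties break toward simpler models (smaller mtry,
then larger node size), then grid order. A simple-learner contract
(logistic regression / linear regression via `stats`) runs the identical
pipeline without tuning and powers the robustness comparators.

## Time-based validation

Supervised rows pair features dated $y$ with the outcome at $y+t$, so the
lagged-effort feature inside a row is a $t$-year lag of its outcome.
Pair-years are indexed by outcome year everywhere. The temporal holdout
is the last outcome year; cross-validation folds are rolling-origin:
assessment year $y$, analysis split the preceding pair-year (sliding
windows; a cumulative option exists because the choice is genuinely open
— sliding was adopted as the literal reading of "the preceding year").
`audit_leakage()` asserts `max(analysis) < assessment` and disjoint
(pixel, outcome-year) keys in every fold; leave-one-ocean-out splits
additionally hold out an entire ocean basin from training.

## Feature engineering conventions

Forty-three features in seven groups (11 MPA-implementation, 12
environmental, 7 geographic, 6 governance, 3 economic, 2 technological,
2 residual). Conventions that the data cannot decide were fixed once:

* **Union coverage.** Per-pixel coverage fractions alone cannot determine
  the union of overlapping MPAs, so records carry an optional `offset`
  and cover the interval `[offset, offset + fraction)` of a pixel; union
  coverage is the measure of the interval union — never a sum, never
  above 1. With the default offset 0, overlapping MPAs nest.
* **Distances.** All "distance to X" features use centroid-to-centroid
  great-circle distances on the 8-connected ocean graph (igraph shortest
  paths), so travel through land is impossible; the Earth radius
  (6,371 km) matches the spherical band formula used for pixel areas.
  Distance to an MPA is 0 for any pixel with positive coverage.
* **Neighborhoods.** "First/second-degree neighbors" are Moore rings 1
  and 2; the ring fraction is the area-weighted mean coverage over the
  ring's cells (land cells count as uncovered; cells beyond the poles are
  dropped; longitude wraps when the grid spans 360°).
* **Dates.** Fraction-of-year counts the implementation day through
  31 December inclusive over the year's true day count (leap-aware):
  1 for full-year coverage, 0 for outside pixels.
* **Sentinels.** Before the first MPA exists, distance takes twice the
  maximum pairwise grid distance and years-since-designation is $-1$ —
  large, constant, documented. Zero-effort pixel-years enter the lag
  feature at one log unit below the smallest positive training value;
  stage 2 never trains on zeros, so the floor only acts as a predictor.
* **Categoricals.** EEZ sovereign labels holding under 1% of the training
  pixels collapse to `"other"`; levels are frozen in the schema at
  training time and reused verbatim at prediction time (the schema hash
  is checked before any prediction).

## The synthetic toy ocean

The generator exists so that every downstream stage has a known truth.
The default world is an 18 × 36 lattice at 10°/pixel (648 pixels, 537
ocean on the default seed) over six contiguous years — large enough to
carry all feature groups, small enough that the full pipeline fits in
seconds. Its layers: contiguous land blobs grown from seeds (ocean
repaired to stay 4-connected), EEZ bands around coastal anchors, ports,
seamounts, a depth field increasing away from shore, smooth AIS-reception
fields, longitudinal ocean basins and latitudinal mesopelagic bands. The
environment has an SST latitudinal gradient with a year-specific anomaly
loaded on the first of two global climate indices (so the field-mean
anomaly and the index are strongly correlated by construction), plus
chlorophyll, wind and annual fuel prices; per-pixel-year standard
deviations emulate aggregation from finer source resolution.

Effort follows the hurdle structure the model assumes: occurrence is
Bernoulli with logistic probability driven by environment, port distance
and seamount proximity plus a pixel random effect; positive intensity is
lognormal around a pixel-specific mean with a multiplicative annual trend
(default 1.02/yr). Behavioral truth enters as a multiplier $m$:

* inside: $m = 1 - \delta_{in}\,c\,\text{cov}$ (defaults
  $\delta_{in} = 0.8$, compliance $c = 1$), scaled by the implemented
  fraction of the year in the implementation year;
* outside: $m = 1 + \delta_{out}\,e^{-d/\lambda}$ with
  $\delta_{out} = -0.3$ and $\lambda = 1{,}100$ km (about one pixel
  width) — a modest, boundary-concentrated decline; the sign is exposed
  because fishing-the-line would flip it;
* optional anticipation multiplies effort in the year before
  implementation for to-be-covered pixels (default 0), and optional fleet
  exit zeroes an EEZ-anchored fleet's contribution once a network covers
  more than a threshold share of its grounds (default off). Both default
  off so the closed form stays exact.

The multiplier shifts the lognormal *location* ($\log m$) and forces
occurrence to zero only when $m = 0$. Consequently the expected percent
change in hours is exactly $100(m-1)$, which `ground_truth_effect()`
returns — the recovery oracle every behavioral test compares against. A
pixel fully inside with $\delta_{in} c = 0.8$ changes by exactly −80%.

The synthetic MPA history defaults to 10 MPAs of ~3 pixels with
implementation dates uniform within the interior years — scaling the real
no-take record (hundreds of MPAs over a ~40,000-pixel ocean) down to the
toy grid, and exercising mid-year implementation routinely. What the
generator does **not** emulate: vessel-level trajectories, gear types,
real coastlines or bathymetry, spatially correlated AIS dropout,
effort-environment feedbacks. Passing tests therefore demonstrate that
the pipeline's machinery is correct and recovers known responses of this
generative family — not that the fitted magnitudes transfer to any real
ocean.

## Scenario engine

Hypothetical networks close whole pixels in ranked order (seeded random;
most-fished by reference-year hours with ties by pixel id; a seeded
uniform sample of unfished pixels; or an externally supplied CSV) until a
target share of ocean *area* is closed, so networks are nested across
targets by construction. Scenario MPAs are implemented on 1 January of
the base year: fraction-of-year 1, years-since 0, future-coverage flags
false. This in-force date is a genuine modelling choice (it interacts
with the anticipation features), which is why `build_network()` takes the
implementation year as an argument rather than hard-coding it.
Predictions for each horizon come directly from base-year features (no
iterative rollout of the lag feature; the per-horizon models are built
for exactly this direct use). Comparisons report pixel-level, regional
(inside/partial/outside), global and distance-binned absolute and percent
differences; pixels with zero BAU prediction are excluded from
pixel-level percent change (their count is reported) but kept in every
aggregate sum, and aggregate percent change is always the ratio of sums.
Distance bins default to 0–1, 1–2, 2–4 and >4 pixel widths from the
network.

## Attribution

Shapley values are estimated per stage (stage 1 on the probability scale,
stage 2 on log intensity — magnitudes are not comparable across stages)
by Monte-Carlo permutation sampling with background marginalisation: each
sample draws a feature ordering and a background row, and accumulates
marginal prediction changes along the ordering. Background rows are drawn
balanced (each appears near-equally often), which integrates background
means with minimal variance — for additive models the closed-form
attribution is recovered essentially exactly. The telescoping sum makes
local accuracy (base + Σφ = prediction) exact up to floating point on
every row, and grouped attribution inherits additivity by summation. The
default grouping has eight groups: previous effort and year individually,
plus the MPA, environmental, geographic, governance, economic and
technological blocks.

## Numerical choices and problem sizes

Degenerate inputs are contracts, not surprises: single-class folds are
skipped with a warning (all skipped is an error), thresholds fall back to
0.5 with a warning only when no cutoff yields a positive F1, empty
residual sets and zero-variance outcomes are errors, unreachable ocean
pixels carry an `Inf` distance plus a warning. All randomness flows from
one master seed through keyed child streams (`child_seed()`), so
regenerating one stage never perturbs another.

The shipped test and acceptance problem sizes are the package's own
choices for interactive runtimes on one CPU: unit fixtures use an 8 × 12
world; the behavioral-recovery and effect-overlap checks use the default
648-pixel world over three seeded replicates with 200-tree forests tuned
over a 4-point grid, pooling the three network rules at the 10% target
for the distance-profile medians. The defaults (500 trees, 10-point grid)
remain the recommended analysis settings.

## Known limitations

* **Counterfactual attenuation.** A scenario pixel combines "MPA fully in
  force all year" with an unsuppressed lagged-effort value. No training
  row can ever look like that: a full feature-year of enforcement
  suppresses that same year's effort, so the fraction-of-year feature is
  definitionally confounded with lag suppression. Tree ensembles
  therefore attenuate the predicted inside-MPA decrease relative to the
  generator's closed-form truth — the acceptance suite measures this gap
  directly (the inside-median recovery check) and the effect is visible
  in the acceptance script's `inside_median_pct_change` versus
  `inside_median_pct_truth`. The bias shrinks with more
  implementation-transition rows (more MPAs, more mid-year dates) and
  with smaller stage-2 mtry, but it is a structural property of
  predicting an out-of-support feature combination, not an implementation
  defect.
* Stage-1 AUC on the toy ocean is modest because occurrence carries a
  pixel random effect that the features only partially proxy; the
  synthetic world is deliberately noisy rather than separable.
* Percent changes are undefined where BAU predicts zero; medians over
  sparsely fished regions (e.g. unfished-rule interiors) rest on few
  pixels.
* The engine predicts *effort*, not catch, revenue or biomass; coupling
  to population dynamics is out of scope.
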