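---
title: "Methods: patch-based hybrid modelling of population spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based hybrid modelling of population spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(patchspread)
```

## The modelling problem

Correlative species distribution models turn presence records and
environmental layers into a continuous habitat-suitability surface, but say
nothing about *when* a spreading population will reach the habitat they
score highly. `patchspread` couples such a surface to a deliberately
minimal mechanistic layer: the suitability map is generalised into discrete
habitat patches constrained to the home-range area of a single individual
(0.06–1.5 km², average ≈ 1 km² for a roe-deer-like ungulate), and spread
emerges from three generic rules — occupied patches produce dispersers in
proportion to patch size and quality, dispersers move across a cost surface
derived from the same map, and they settle in patches below carrying
capacity. Because patches are individual-sized, "patch occupied" is a
statement about a single home range, which keeps the output interpretable
at the scale of management decisions (individual woodlands, corridors)
while demography stays almost parameter-free.

## Patch delineation

All four methods share three ingredients: a suitability threshold θ
(default 0.56, the maxSSS criterion; thresholding is *inclusive*, cells
with H ≥ θ are suitable), summarisation of member-cell values (per-patch
mean suitability is always computed from the *continuous* surface; integer
scaling to 0–100 happens only at export), and the home-range size bounds
(`size_class_bounds()`: small < 0.06 km², 0.06 ≤ medium ≤ 1 km²,
large > 1 km²; the area filter is strict — exactly 0.06 km² survives,
consistent with 0.06 being a medium patch).

* **Grid** (`delineate_grid()`): 1 km blocks anchored at the raster origin
  (anchoring to the raster rather than a national grid is a package
  decision; the source material does not specify). Blocks whose mean falls
  strictly below θ are dropped.
* **Voronoi** (`delineate_voronoi()`): points are sampled over the whole
  non-nodata extent at ~1 pt/km² — density is computed over the full
  extent, not just suitable area, matching the reported point count per
  total area — weighted by suitability, with 150 m minimum spacing (the
  radius of the smallest home range). Thiessen polygons are rasterised
  directly by nearest-point assignment of cell centres (ties to the lower
  point index, for determinism), which achieves the boundary-alignment
  that GIS workflows get from a vector→raster→vector round trip.
* **Contiguity** (`delineate_contiguity()`): threshold, 8-connected
  labelling (row-major first-encounter label order), area filter. No upper
  size limit — this method deliberately exhibits the *mega-patch problem*:
  an occupied patch implies presence across its whole extent, so very
  large patches overestimate spread.
* **Vor-Con** (`delineate_vorcon()`): contiguity patches classified by
  size; small dropped, medium kept, each large patch partitioned by a
  Voronoi tessellation of points sampled *within that patch only*
  (n = max(2, round(area in km²)); the minimum of 2 guarantees an actual
  split). Sub-patches never span two parents and their union equals the
  parent exactly — a property the tests assert cell-for-cell.

The balanced-point sampler (`sample_balanced_points()`) replaces a
proprietary GIS tool. It draws a weighted sample without replacement using
Efraimidis–Spirakis exponential keys, accepts candidates greedily under
the minimum-distance constraint (spatial-hash lookup, 50× oversampling
cap, warning when the target is unreachable), and jitters each accepted
point uniformly within its cell so regular grids never produce degenerate
collinear tessellation input.

## Population dynamics

Three stages: juveniles (age 0), dispersers (age 1), adults (age ≥ 2).
Baseline fecundity Φ, all survival probabilities, reproduction probability
and emigration probability default to 1; maximum age 1000 years makes
local extinction essentially impossible, so occupancy can only accumulate.
Regulation comes solely from density-dependent exponential decay

x = x₀ · e^(−bN),  1/b = 1,

with N the raw count of individuals in the patch. Offspring counts are
Poisson with this density-dependent mean (the distribution is a package
choice; only the mean is specified upstream, and the tests check the
Monte-Carlo mean against the closed form). By default the decay acts on
**fecundity only** (`dd_on_survival = FALSE`): applying it to survival
with b = 1 would give a lone resident survival e⁻¹ ≈ 0.37, contradicting
the intended near-zero extinction probability; a flag restores it for
exploration. Carrying capacity is K = max(1, round(area × mean suitability
× k_max)) with k_max = 1 individual per fully suitable km² — unspecified
upstream, chosen so a typical fully suitable 1 km² home-range patch holds
one adult, which is what "individual-sized patch" means; it is
configurable.

The within-year event order is: reproduce → juveniles develop into
dispersers → obligate emigration → transfer and settlement → ageing, with
the census after all events. Settlers join their destination patch
immediately (they count towards N for later settlers the same year) and
reproduce from the next year. Every emigrant ends the year settled or
dead; the per-year conservation identity `emigrated = settled + died` is
logged and asserted by the tests.

## Movement (stochastic nearest-neighbour transfer)

Dispersers start at a uniformly drawn natal-patch cell and take discrete
steps to one of 8 neighbours. For each direction the *effective cost* is
the inverse-distance-weighted mean (weights 1/d) of cell costs along the
directional ray out to the perceptual range (PR = 400 m = 4 cells at
100 m; PR is quantised by truncating division, so 440 m still perceives
4 cells). The ray truncates at the first off-map or nodata cell; if even
the adjacent cell is off-map the direction is disallowed — nodata (sea,
out-of-region) is excluded from the movement neighbourhood entirely
rather than assigned a traversable cost, since dispersers should not walk
on unmapped area. Step weights combine inverse effective cost with
directional persistence DP = 5 as

w(dir) = DP^((4−k)/4) / effective_cost(dir),

where k is the number of 45° increments between the candidate direction
and the current heading (straight ahead DP¹, right angle DP^½, reverse
DP⁰ = 1; no persistence on the first step). The exponent schedule is a
package decision: the upstream description fixes only the endpoints, and
any monotone rule satisfies it, so this one is documented and
unit-tested. A disperser enclosed entirely by off-map cells dies.

The step budget is expressed in cardinal-step units and **diagonal steps
consume √2 units**, so the maximum possible Euclidean displacement is
exactly max_steps × cell size (200 × 100 m = 20 km), attained by a
straight cardinal path — pure step counting would let diagonal paths
reach 28.3 km, breaking the stated step↔distance equivalence. Dispersers
that exhaust the budget die (a failed long-distance dispersal); natal
settlement is disallowed (emigration is obligate), re-entry into the
natal patch is allowed but never triggers settlement; in any other patch,
settlement is evaluated on every step spent inside it, with logistic
probability 1/(1 + exp(−α(N/K − β))), α = −100, β = 1 — ≈1 below
capacity, 0.5 at capacity, ≈0 above.

A practical consequence of inverse-cost weighting, discovered while
validating the simulator and worth knowing when preparing inputs: a
*step-function* cost edge of ~10× contrast (e.g. cost 5 habitat abutting
cost 75 matrix) is nearly impermeable — walkers skim the cheap side until
the budget dies. Gradual cost gradients, which real suitability surfaces
produce naturally, are escapable because directional persistence
dominates shallow slopes. The synthetic generator therefore stamps
planted patches with a cone profile and a smooth skirt (below), and users
supplying hand-made binary suitability maps should expect unrealistically
low inter-patch transfer.

## Occupancy, initialisation and duration

Replicate r is seeded with `seed + r − 1`; 10 replicates by default.
Initial patches (those within a 10 km buffer of the centroid of
first-period presences for historic evaluation, or within evaluation-grid
cells containing presences for novel regions) start at N = K adults
(initial abundance is unspecified upstream; starting at capacity makes
the source pool maximally and immediately productive). When no duration
is given, a pilot replicate runs until every patch is occupied (capped at
600 years) and reporting checkpoints divide that duration evenly — so the
final checkpoint sits near complete occupation, mirroring the "run until
full occupancy" protocol. Binary per-replicate occupancy (any adults) is
averaged; mean occupancy ≥ 0.7 (7 of 10 replicates) marks a patch
occupied. Checkpoints are reported as years; mapping simulated timesteps
onto calendar decades is left to the user, since the upstream protocol
matches simulated to observed timesteps by index only.

## Evaluation

Observed ranges are built from *cumulative* presences per period
(observed ranges never shrink; using per-period points instead would let
them), as minimum convex polygons intersected with the 10 km evaluation
grid (ObsRange), alongside the cells actually containing records
(ObsPresences ⊆ ObsRange). Periods with fewer than three non-collinear
points fall back to presence cells with a warning. Sensitivity
TP/(TP+FN), specificity TN/(TN+FP) and TSS = sens + spec − 1 use the
standard definitions (the upstream prose parentheticals describe
precision-like quantities; the standard definitions are implemented and
the discrepancy documented rather than guessed). True negatives exist
only inside the declared evaluation region. Timesteps where a component
is undefined (prediction or observation covers the whole region, or is
empty) are reported as missing and excluded from the summary, whose
`n_used` column says how many timesteps contributed. TSS falls over
timesteps by construction: as the predicted range grows relative to the
region, over-prediction (vs ObsPresences) and under-prediction (vs
ObsRange) are penalised ever harder — a property of the evaluation
design, not a model defect.

The sensitivity harness (`sensitivity_analysis()`) perturbs PR, DP and
the step budget by ±10 % under common seeds and a common duration (fixed
from the base run's auto duration) and compares final-checkpoint occupied
cell sets by Jaccard similarity; comparing near-complete ranges mirrors
the upstream protocol, which ran simulations to complete occupation
before comparing predictions.

## Synthetic landscapes: what they do and do not establish

`generate_hsm()` builds spatially autocorrelated suitability (white noise
convolved with a Gaussian kernel via FFT — circular convolution; simple
and dependency-free, at the cost of wrap-around correlation at opposite
edges, irrelevant at the tested autocorrelation lengths) rescaled to a
target mean/SD, optionally capped below θ so that only planted patches
are suitable. Planted blobs have an exact footprint (cell centres within
the stated radius), a linear cone from peak (centre) to edge value
(radius) and an exponential skirt outside — exact ground truth for
delineation tests, smooth gradients for the movement model.
`generate_presences()` emulates spatiotemporally clustered records
radiating from an origin with suitability bias. All generators are pure
functions of their seeded spec.

The four canonical fixtures state a world once and do not move with test
outcomes: a two-patch corridor strip (3 × 13 cells; patches at 0.65,
corridor at 0.50 — sub-threshold habitat that is still the cheap route),
a 100 km² mega-patch block spanning six 10-km cells, an archipelago of 20
medium blobs at graded distances (1.8–9 km) in a permeable matrix
(suitability ≈ 0.5), and a uniform sub-threshold surface. The matrix
permeability and smooth patch edges encode the assumption that the
landscape between patches is traversable mid-quality habitat, as for a
generalist ungulate in an agricultural matrix. A green test suite
therefore establishes internal correctness (oracle equivalence, exact
planted-truth recovery, conservation, determinism, the mega-patch
ordering, parameter insensitivity) on landscapes *with* these
properties; it does not establish calibration against any real dataset,
nor behaviour in hostile or highly fragmented matrices where the
cost-cliff effect would dominate.

## Numerical conventions

* Rounding is half-away-from-zero everywhere user-visible (integer
  scaling, carrying capacity, point counts), avoiding platform-dependent
  banker's rounding.
* Costs are floored at 1 (the inversion formula yields 0 at suitability
  100, which would make inverse-cost weights undefined); nodata cells are
  off-map, not high-cost.
* Voronoi distance ties go to the lower point index; labelling and patch
  re-indexing are row-major first-encounter, so every labelled structure
  is deterministic.
* Fishnet cells are half-open ([x, x+cs) × [y, y+cs)), so every point and
  cell centre maps to exactly one cell; grids are anchored to the raster
  origin so 1 km and 10 km cell boundaries coincide with 100 m cells.
* The settlement logistic clamps its exponent at ±700 to avoid overflow;
  with the default α this changes nothing observable.
* Stage seeds in the pipeline derive from the master seed by fixed
  offsets (delineation +1000·index, simulation +2000·index), so any stage
  can be re-run alone, reproducibly.

## Known limitations

Single-band ASCII-grid raster I/O only (no GeoTIFF, no reprojection —
inputs must share one grid); asexual, age-homogeneous demography with no
environmental stochasticity or dynamic landscapes; movement costs equal
inverted suitability rather than independently observed resistance;
evaluation depends on presence-only comparators that bracket rather than
measure the true range. These mirror the scope of the modelling approach
itself rather than shortcuts in its implementation.
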