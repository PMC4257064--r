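---
title: "Modeling deforestation risk with deforisk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deforestation risk with deforisk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deforisk)
```

## The problem

Tropical deforestation frontiers — the motivating case is the Madre de Dios
region of the Peruvian Amazon after the paving of its trunk highway — clear
forest in a strongly non-random way: along roads and rivers, near towns and
earlier clearings, and preferentially in land without protective
designation. A REDD+ program needs three things from a risk analysis: a
*soft* map of per-cell clearing risk, a *hard* map of the specific area
expected to be lost by a horizon year under business-as-usual (BAU) rates,
and the CO2 consequence of that loss. `deforisk` implements that chain and,
because classified change rasters are rarely distributable, ships a
synthetic landscape generator with the same statistical structure so every
stage can be exercised and tested.

## Rates and projection

Annualized change is measured on the logarithmic scale,
$$ r = \frac{1}{t_2 - t_1} \ln\frac{A_2}{A_1}, $$
with $A_1, A_2$ the forest areas at the two assessment dates. The rate is
kept signed internally (negative = loss) and formatted as positive percent
per year, the field's reporting convention. The FAO compound form
$q = (A_2/A_1)^{1/(t_2-t_1)} - 1$ is also provided; the two agree to
$r^2/2$, which at sub-percent rates is order $10^{-6}$ — the package reports
the logarithmic form and keeps the FAO column for comparison, since nothing
downstream is sensitive to the choice. Projection is the exact inverse,
$A(t) = A_0 e^{rt}$, so rate estimation followed by projection over the same
period reproduces the input areas to machine precision — a property the test
suite asserts.

Carbon accounting multiplies lost area by a median forest carbon density
(default 113 Mg C/ha, an above-ground Amazonian value) and converts with the
stoichiometric ratio 44/12 ≈ 3.6667 Mg CO2 per Mg C. Reports in this
literature often print the rounded factor 3.67, but their totals are only
consistent with 44/12; the default is therefore the exact ratio, with the
rounded factor selectable through `carbon_params(co2_per_c = 3.67)`.
Below-ground, soil and deadwood pools are deliberately out of scope.

## Consensus change and sampling

With several classifiers observing the same landscape, a cell is accepted as
deforested only when *every* source maps it forest at the period start and
non-forest at the end; it is stable forest only when every source maps
forest at both dates; everything else — disagreement or cloud/nodata in any
source — is undetermined. The asymmetry is intentional: cloud cover makes
absences unreliable, so undetermined cells are never treated as "no change".
This makes consensus monotone (adding a source can only shrink the
deforested mask) and conservative: on synthetic triplets the consensus mask
has higher precision than any single source.

Presence and background points are single cell centers sampled uniformly
without replacement — one point per cell, so the model never sees duplicate
presences. The conventional presence count is 500 but the parameter is
free; nothing in this implementation inherits the historical software
memory cap that once forced 500.

## Accessibility

The accessibility index summarizes how fast the landscape can be reached
from settlement. A friction surface assigns each cell a traversal cost of
`60 / (1000 * speed_kmh)` minutes per meter, where the speed is the
land-cover category speed, overridden by the river speed on river cells and
the road speed on road cells (road wins), and divided by the slope penalty
`1 + slope/s0`. The penalty form (half speed at `s0 = 30` degrees by
default) is a configurable design choice: published friction coefficients
for the motivating study are not available in its body, so the shipped
speed table (forest 2, cleared 4, river 10, dirt road 30, paved road 60
km/h; `inst/extdata/friction_default.tsv`) is an explicitly editable
placeholder calibrated to common Amazonian field-travel figures. Variable
contribution analyses in this setting show slope contributing on the order
of 1 %, so results are insensitive to the penalty's exact form.

Travel time is the least-cost cumulative time from source cells (towns by
default; roads and rivers act through low friction rather than as sources —
one clear convention, configurable) over 8-connected moves, each move
costing step length (cell size, ×√2 diagonally) times the mean of the two
cells' costs — standard cost-distance semantics, pinned precisely so an
independent Dijkstra oracle can verify it. The index is
`exp(-time/tau)` with `tau` defaulting to the median travel time, placing
the landscape's median cell at 0.37; any strictly decreasing transform
would order cells identically, which is what the downstream model consumes.
Epoch-specific friction tables (e.g. a dirt→asphalt upgrade) reproduce the
strict travel-time decrease an upgraded corridor should show.

## The maximum-entropy risk model

Deforestation presences are modeled like species occurrences: find the
distribution $q(x) \propto e^{\lambda \cdot f(x)}$ over background cells
that matches presence feature means under regularization slack. Features
per continuous variable are linear, quadratic, and 8 forward hinges at
equally spaced knots, all min-max scaled to [0, 1] using background-derived
constants (stored, and clamped for prediction at new points); categorical
variables get one indicator per category. The fit maximizes the penalized
mean presence log-likelihood
$$ J(\lambda) = \overline{\lambda\cdot f}_{\text{presence}} - \log Z(\lambda)
   - \sum_j \beta_j |\lambda_j|, $$
by proximal-gradient ascent with backtracking, which guarantees a monotone
objective; iteration stops when the improvement falls below 1e-7 or at 500
iterations. At the optimum the KKT conditions bound every feature's fitted
expectation within $\beta_j$ of its presence mean; the model object carries
this slack, and tests assert it on every fit with a numerical allowance of
2.5e-4 consistent with the stopping rule. Default $\beta$ (0.05
linear/quadratic, 0.5 hinge, 0.25 categorical, scaled by
$1/\sqrt{n_{\text{presence}}}$) follows the convention that more presences
permit tighter matching; the exact values are exposed because "default
settings" of the historical tool are not a specification. Product and
threshold features are omitted: with 2–5 explanatory variables they add
little and would complicate the brute-force oracle tests that pin the
optimizer's correctness.

Prediction offers the raw relative occurrence rate $q(x) N_{\text{bg}}$ and
the default logistic risk $q e^H / (1 + q e^H)$, with $H$ the entropy of the
fitted distribution; an uninformative model scores 0.5 everywhere. Model
quality is summarized by replicate runs (default 70/30 presence
subsampling; subsampling rather than bootstrap so the held-out AUC is a
proper test statistic), scoring held-out presences against background
pseudo-absences — the standard presence-only AUC. Variable importance is
permutation-based: the drop in training gain when one variable's values are
permuted across the pooled points, averaged over 10 seeded permutations and
normalized to 100. The historical tool's "percent contribution" is
path-dependent on its training algorithm and cannot be replicated exactly;
permutation importance is the stated, reproducible substitute, so published
contribution tables are qualitative rather than exact targets.

## Hard classification

"Select the highest risk values until the projected loss area is reached,
rounding to whole percent" is read as a threshold ladder
{1.00, 0.99, …, 0.00}: the chosen p* is the ladder value whose selected
area (forested, non-nodata cells with risk ≥ p*) is nearest the target,
ties resolving to the higher threshold (the smaller selection). The ladder
is built from integer arithmetic so 0.70 on the ladder equals a risk of
0.70 exactly. Only the logistic scale is thresholded — quoted risk values
like "59 %" live on it. The implementation is verified against an
exhaustive scan of all 101 ladder values.

## Validation

Predicted risk is validated against *later* observed change: risk at the
centroids of consensus-deforested patches of at least 10 ha (inclusive,
8-connected, centroid = mean of member cell centers snapped to the nearest
cell) versus risk at random study-area points restricted to stable forest.
No exclusion buffer is applied around deforested patches when drawing
no-change points; users wanting spatial separation should enforce it
upstream. The groups are contrasted with a Mann-Whitney U test: U counts
cross-pairs with half-weight ties, the reported statistic is
min(U, n₁n₂ − U), and the two-sided p-value uses the exact U distribution
when there are no ties and n₁n₂ ≤ 400, otherwise the normal approximation
with tie and continuity corrections.

## What the synthetic generator does and does not emulate

`sim_config()` defines a 200 × 200 grid of 1-ha cells (40,000 ha) — large
enough for rate recovery within binomial error yet small enough that the
full pipeline runs in seconds. Roads and rivers are wiggly corridors
crossing the grid, towns sit on the network with small pre-period clearing
footprints, slope is a smooth random field (0–25°), and five designation
zones (protected, indigenous reserve, concession, mining, public) tile the
grid as a Voronoi partition. Clearing is simulated year by year: each
remaining forest cell is cleared with probability following
`logit w = b0 + b_acc·acc − b_dist·(dist/300 m) + offset_zone`, rescaled so
the expected cleared fraction matches the annual target rate (default
0.003, the strong recent BAU rate of the motivating frontier), with the
distance-to-prior-deforestation surface recomputed between years so
clearing spreads contiguously from existing clearings — the contagion that
produces the ≥ 10-ha patches the validation protocol needs. The default
coefficients (b0 = −14, b_acc = 18, b_dist = 12) were chosen once so the
generated landscape shows the structure frontier studies report: clearing
concentrated along corridors, discrimination around AUC 0.9 or above, and
accessibility carrying roughly 90 % of the explanatory power. Classifier
views flip labels independently at per-source noise rates (2–5 %) and blank
blob-shaped cloud masks (5–10 %), drawn as top quantiles of a smooth field
so the masked fraction is honored almost exactly.

What it does *not* emulate: realistic geomorphology or hydrology, road
network growth, economic agents, classifier errors that correlate between
sources or with land cover, and multi-date classifier inconsistencies.
Passing pipeline tests therefore demonstrate that the machinery recovers
known structure from data shaped like the assumed process — not that the
model is correct for any particular real landscape.

## Numerical and degenerate-input conventions

* All grids in an analysis must share shape, cell size and origin; nodata
  (`NA`) cells never contribute to areas, distances, samples or fits.
* Distances are center-to-center; rows are indexed from the top; patches
  use 8-connectivity (the raster-GIS convention; fixed so centroid and
  patch tests are unambiguous).
* `distance_transform` on an all-false mask, `consensus` with zero sources,
  `cost_distance` without passable sources, a hard-map target above forest
  area, and presence samples larger than the deforested cell count are all
  errors with explanatory messages; an all-constant feature set yields the
  uniform model with a warning; a single replicate run reports SD 0 with a
  warning.
* ESRI ASCII grids round-trip doubles exactly (17 significant digits);
  GeoTIFFs are single-band uncompressed float32 with NaN nodata, exact for
  float32-representable data, and cross-validated against an independent
  Python TIFF reader in the tests.
* All internal randomness flows through per-call seeded streams that leave
  the caller's RNG state untouched; the same seed reproduces every product
  bit for bit.

## Problem sizes used by the test suite

Unit tests use toy grids (≤ 25 × 25) against brute-force oracles
(all-pairs distances, BFS labeling, dense Dijkstra, grid-searched maxent
objectives, permutation Mann-Whitney). Pipeline-level tests run the default
200 × 200 landscape with 5 replicate fits across five seeds; the replicate
count is kept modest because the AUC/contribution means stabilize quickly,
and `run_pipeline(k = ...)` scales to the 100-replicate convention when
desired.

## Known limitations

* Planar grids only: no CRS handling, reprojection or vector I/O; inputs
  must be co-registered upstream.
* The friction coefficients and the slope-penalty form are placeholders to
  be replaced with locally calibrated values.
* Percent contribution is permutation-based and will divide credit between
  strongly correlated variables (accessibility and distance-to-prior
  deforestation are correlated by construction in the generator, as in
  real frontiers).
* The hard map is a single-horizon allocation, not a year-by-year
  simulation of loss, and its risk ranking is assumed stationary over the
  projection horizon — the BAU assumption.
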