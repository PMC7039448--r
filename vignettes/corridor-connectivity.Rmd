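---
title: "From occurrence points to dispersal corridors: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From occurrence points to dispersal corridors: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorsdm)
```

# The problem

A large carnivore recolonising a fragmented landscape is detected in two
separate study areas — a riverine plain and a belt of hills — separated by an
intensively cultivated matrix. The management question is where dispersal
corridors between the two areas are most likely to run. `corridorsdm`
implements a complete analysis chain for this question:

1. relate presence and pseudo-absence points to the *fractional cover* of
   land-cover classes in a small buffer (habitat selection at the scale
   relevant to movement);
2. fit an ensemble of species distribution models (SDMs) per study area and
   project it over the whole landscape;
3. integrate the two maps, convert habitat suitability into a *resistance
   surface*; and
4. summarise connectivity synoptically with factorial least-cost paths and
   cumulative resistant kernels.

Because real telemetry or land-cover data cannot ship with the package, a
first-class synthetic-landscape and virtual-species module generates inputs
with the statistical structure the analysis assumes, so every stage is
testable end to end.

# Covariates

For a probe point, the fraction of each land-cover class is computed over
all raster cells whose *center* lies within `radius_m` (default 100 m) of
the point. This cell-center rule — rather than area-weighted polygon
intersection — was chosen because it is exactly recomputable: the
moving-window projection (`fractional_cover_stack()`) and the per-point
training computation (`fractional_cover()`) use the same disc of integer
cell offsets and agree to machine precision, which the tests exploit. The
discretisation error vanishes as cells shrink relative to the buffer.

Fractions over all classes sum to one at any point because the classes
partition the landscape. Two consequences deserve attention:

* **Compositional collinearity.** The full set of fractional covers is
  linearly dependent with the intercept. The pairwise Pearson screen
  (`collinearity_screen()`, flag at |r| > 0.60, n−1 variance denominator)
  cannot see this sum constraint; it is tolerated exactly as in standard
  ensemble-SDM practice. The ridge stabiliser in the GLM makes the fit
  well-posed; *predictions* are unaffected, but individual coefficients are
  identified only up to the compositional constraint and should not be
  interpreted in isolation.
* The screen reports; it never drops variables. Removing a variable is a
  configuration action, because the reference analysis states only that the
  check passed.

# The three distribution models

All three fit presence (1) versus pseudo-absence (0) rows of a covariate
table and predict an occurrence score in [0, 1].

**GLM.** A binomial-logit model fitted by iteratively reweighted least
squares with a small ridge penalty (1e-6) on the slopes. The ridge exists
for one reason: under complete separation the unpenalised MLE diverges,
and a projection across a landscape must never produce infinite
coefficients. Convergence is declared when the largest coefficient change
drops below 1e-8, with a cap of 100 iterations (non-convergence is a
warning carrying the iteration count, not an error). Away from separation
the fit agrees with `stats::glm` to four decimals (tested). Linear terms
only by default; a quadratic option exists behind a flag.

**GBM.** Stagewise gradient boosting on the logistic deviance with
depth-limited trees. Defaults — 500 stages, learning rate 0.05, depth 3,
bag fraction 1 — are declared package defaults, not values recovered from
any reference analysis, which names none. Training deviance is
non-increasing across stages (tested). Fitting is single-threaded so
results are bit-reproducible.

**MaxEnt.** A Gibbs distribution over the background (pseudo-absence)
cells, `q(x) ∝ exp(w·f(x))`, with linear + quadratic features of the
covariates, fitted by maximising the L1-penalised log-likelihood with an
accelerated proximal-gradient (FISTA) solver. At zero penalty the fitted
distribution reproduces the empirical presence means of the features — the
defining moment property of maximum entropy — verified in a test against
direct numeric optimisation. When no penalty is supplied it is chosen by
held-out Gibbs log-likelihood on a 20% presence holdout, then the model is
refitted on all presences. Predictions use a logistic output form,
`plogis(w·f(x) − α)` with `α` the log of the mean background exponent, so a
cell indistinguishable from the average background scores 0.5. Hinge and
threshold features of the reference MaxEnt implementation are omitted;
the feature set is config-expandable.

# Evaluation, ensemble, importance

Models are evaluated over three replicated stratified splits, 75% training
and 25% testing, with AUC (Mann–Whitney form, ties counted one half) and
TSS (maximum over candidate thresholds of sensitivity + specificity − 1;
candidates are midpoints between sorted unique scores plus the two
infinities, so all-tied scores give exactly 0). Stratification by label
preserves the presence:pseudo-absence ratio and avoids degenerate splits;
splits are drawn once per seed so all model kinds see identical partitions.

The ensemble predicts the weighted mean of its members, weight proportional
to each member's mean *test* AUC, normalised to sum to one — no exponent,
no decay, and no exclusion floor, because the reference procedure states
weighting only. Variable importance follows the randomization convention
of the ensemble-modelling literature: predictions on the original table are
correlated with predictions after permuting one column; importance is
`1 − |r|` averaged over 10 permutations (seeded). A variable the model
ignores scores exactly 0.

# Suitability maps

Projection evaluates the per-area ensemble on every cell's buffer covers
and scales to the declared 0–1000 suitability range. Before integration,
pixels of land-cover classes not available to an area's model (the
hills-only class in the plain model and vice versa) are set to 0; the two
maps are then merged by per-pixel maximum and normalised to 0–1 **by
dividing by the declared 1000 ceiling**. Min–max normalisation was
rejected deliberately: it would let the observed maximum redefine the
scale and break comparability between maps. The "suitable fraction" uses
a strict inequality (occurrence probability *higher than* 0.5).

Note that an SDM's predicted probability scale depends on the
presence:background ratio of its training data; with 96 and 71 presences
against 300 and 500 pseudo-absences, the two area models sit on different
baselines. The per-pixel-max integration is robust to this (the better
model wins where it is confident), but the area above 0.5 should be read
as a scale-dependent summary, not an absolute occupancy estimate.

# Resistance and connectivity

Suitability h becomes resistance through the one-parameter negative
exponential `R(h) = r_max^(1−h)` (equivalently `exp(ln r_max · (1−h))`),
with `r_max = 100` by default. This is the unique single-parameter
exponential hitting both anchor points R(1) = 1 (ideal habitat costs its
metric length) and R(0) = r_max, and it keeps most of the landscape
permeable while only strongly unsuitable pixels become expensive — the
behaviour that motivates exponential over linear conversion for a vagile
species.

Sources are the centroids of 1-km grid cells containing at least one pixel
with suitability above 0.5 (cells clipped at the raster edge use their
true pixel set and clipped-extent centroid). In the northern massif —
where occupancy is sporadic rather than established — qualifying centroids
are thinned to one per 5-km block, keeping the centroid whose cell has the
highest maximum suitability (ties resolved by lowest grid row, then
column).

The cost graph connects 8-neighbouring traversable cells with weight
`cell_size × (R_i + R_j)/2`, diagonals additionally × √2; nodata cells
carry no edges, so paths cannot cut corners through them. Shortest paths
are exact Dijkstra (via igraph); for a fixed graph the returned path is
deterministic, so whole-pipeline outputs are bit-reproducible under a
fixed seed. The test suite checks costs against an independent
brute-force relaxation oracle on random rasters.

*Factorial least-cost paths*: every unordered source pair whose
**Euclidean** separation is within the scenario threshold (100 km for the
low-dispersal scenario, 850 km for high) contributes +1 to every cell of
its least-cost path; pairs with unreachable endpoints are skipped and
reported. The Euclidean filter follows the reference wording even though
paths themselves are cost-based; a cost-distance filter is available as an
option. *Cumulative resistant kernels*: around each source,
`exp(−d²/(2σ²))` of cost distance d, truncated at D = threshold × 1000 m,
summed over sources. The bandwidth σ = D/3 is a declared package decision
(no bandwidth is stated by the reference software description); it leaves
under 1.2% of the Gaussian mass beyond the truncation radius. The
movement extent is the percentage of cells with density strictly above 0;
whether a higher display threshold was used in the reference maps is not
recoverable, so 0 is the default and the threshold is an argument.

# The synthetic landscape and virtual species

The generator emulates the *structure* the analysis assumes, not any real
geography: three horizontal strata (woodland-dominated northern massif,
arable/rice central plain, mixed southern hills); two rectangular study
sub-areas (a plain "ticino" analogue and a hills "apennine" analogue);
two classes confined to a single sub-area (rice paddies in the plain
area, vineyards in the hills area); and 1-cell-wide rivers crossing the
plain so that a high-suitability riparian corridor can exist.

Patchiness comes from smoothed Gaussian random fields: one iid noise field
per class is smoothed at `patch_scale_cells`, rank-transformed to a
uniform margin, and each cell takes the class maximising `log(u_k)/w_k`
for stratum target fraction `w_k` — a construction that draws class k with
probability essentially `w_k` per cell (exactly so for independent
uniforms) while inheriting the fields' spatial autocorrelation. Realized
fractions therefore concentrate on the targets as patches shrink relative
to the raster (tested at ±0.05 on 200×200 rasters).

Defaults, fixed once as the package's reference conditions:

* presences 96 (plain area) and 71 (hills area); pseudo-absences 300 and
  500, uniform at cell centers, proportional to the sub-area surfaces and
  *not* excluded from presence cells (plain random generation);
* a 100-m covariate buffer, 0.60 collinearity flag, three 75/25
  replicates, 0.5 suitability cutoff, 1-km source grid, 5-km massif
  rarefaction, 100-km and 850-km scenarios, r_max 100;
* `patch_scale_cells = 5` (500 m at the default 100-m cells), matching the
  25-ha minimum mapping unit of the pan-European land-cover product the
  covariates emulate;
* virtual-species coefficients describing a strongly woodland-associated,
  urban-averse carnivore that follows riparian cover (woodland +4,
  transitional woodland +2, water +2.5, meadows +1, complex cultivation
  +0.5, arable −1.5, vineyards −0.5, rice paddies −2.5, urban −4,
  intercept −2 on the log-odds scale). A weaker specialist produces maps
  whose suitable area collapses under the unbalanced presence:background
  ratios above; a strong specialist is also the ecologically defensible
  reading for a recolonising wolf-like carnivore.

What the generator does **not** emulate: real minimum-convex-polygon study
boundaries, roads and hydrology beyond the toy rivers, observation bias
along transects, spatial clustering of detections, and imperfect
detection. Passing tests therefore demonstrate that the *method chain* is
implemented correctly and behaves as theory predicts on data satisfying
its assumptions — they are not evidence about any real landscape.

# Numerical choices and degenerate inputs

* IRLS ridge 1e-6 on slopes only; weights floored at 1e-12.
* FISTA with backtracking line search; a non-finite objective is treated
  as a violated bound (step halving), momentum restarts on overshoot, and
  the step size is floored, so the solver is robust to the near-degenerate
  geometry of strongly separable presences.
* Zero-variance covariates are an error in the fitters (the caller must
  drop them); the pipeline drops them per training split, because a rare
  class can be constant within one replicate even when variable overall.
* Pseudo-absence sampling is with replacement over mask cells (duplicate
  points are legitimate and retained by the importer).
* One root seed deterministically spawns per-stage seeds
  (`spawn_seeds()`), so any stage can be re-run in isolation; manifests
  record per-artifact MD5 checksums and re-running a configuration
  reproduces them bit for bit (tested).
* Raster I/O uses the plain-text ESRI ASCII grid format; occurrence
  tables are CSV, with the supplementary workbook layout (x, y, area,
  presence flag; XLSX) accepted via a python/openpyxl bridge. The
  importer sniffs headers and fails loudly with the offending row rather
  than guessing.

# Problem sizes

The reference configuration (`default_run_config()`) runs a 200 × 200-cell
landscape at 100-m resolution — large enough for ~200 sources and visible
corridor structure, small enough that the full pipeline completes in well
under a minute. `demo_run_config()` (64 × 64, 60 presences per area) is
the quick end-to-end configuration used for smoke checks. Both are
package choices; nothing in the method limits raster size beyond memory
and the O(sources × cells log cells) shortest-path work.

# Known limitations

* No circuit-theoretic (random-walk) connectivity, corridor-width
  buffering, or barrier prioritisation; no committee-variance uncertainty
  maps; no spatial block cross-validation.
* The `> 0.5` suitable fraction inherits the prevalence of the training
  design (see above).
* Coefficients of the compositional GLM are not individually
  interpretable; use the randomization importances instead.
* Equal-cost path ties are broken deterministically by the graph library,
  not by an externally specified rank rule; determinism, not a particular
  tie winner, is the guaranteed property.
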