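---
title: "Coupling step-selection functions with an individual-based walk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling step-selection functions with an individual-based walk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfwalk)
```

`ssfwalk` models winter movements of a large browsing herbivore (the
motivating system is woodland caribou on managed boreal landscapes) as a
biased correlated random walk whose per-step bias is a fitted
step-selection function. This vignette is the package's own account of the
science: the submodels and their assumptions, the constants and where their
defaults come from, what the synthetic generators do and do not emulate,
and the numerical and design choices a maintainer should know about.

## 1. The movement model

Time advances in 4 h steps (the GPS fix interval; 6 steps per day). At each
step an individual considers 21 candidate steps: lengths and turning angles
are independent resamples of the pooled empirical distributions of all
individuals' winter steps, so the geometry of candidate movement is
data-driven rather than parametric. Each candidate is scored

$$w(\mathbf{x}) = \exp(\boldsymbol\beta^\top \mathbf{x}),$$

with ten covariates evaluated at the candidate's end cell and along its
direction:

| covariate | meaning | units |
|---|---|---|
| `cos_t_mem` | cosine of the minimum angle between the step and the directions to remembered patch centroids | — |
| `g_over_l` | hypothetical energy gain at the end cell over the energetic cost of the step | — |
| `cover` | canopy cover of the end cell | % |
| `altitude` | end-cell elevation | m |
| `edge` | canopy-cover gradient magnitude at the end cell | %/cell |
| `road_term`, `recent_cut_term`, `regen_cut_term` | cos θ to the nearest feature × linear proximity kernel f(D) | — |
| `gl_x_de`, `cover_x_de` | interactions of `g_over_l` and `cover` with the 72 h energy balance ΔE | — |

A selection rule turns scores into a choice: `best` (argmax), `best90`
(argmax with probability 0.9, otherwise uniform over all 21), `roulette`
(probability ∝ w/(1+w), the logistic transform, normalised over the
candidate set — we normalise to obtain a proper distribution rather than
using the logistic values as acceptance probabilities), `crw` (uniform — the
null model), and `ssf` (probability ∝ w). The fifth rule is this package's
addition: sampling proportional to the raw score is exactly the generative
model of the conditional logistic likelihood, which makes the
simulate → replay → refit loop a well-posed parameter-recovery experiment;
the four classical rules are implemented exactly as described above and
are the ones used for pattern validation.

After moving, the individual feeds at its new cell, the cell's lichen is
depleted by the grams ingested (never below zero — ingestion is capped by
what the cell holds, which is what makes the mass-balance invariant exact),
the net energy G − L is pushed onto an 18-entry FIFO ledger (3 days), and
the memory and heading update. Individuals act in series within an
iteration, so depletion is order-dependent; the order is fixed (id order)
and all randomness flows from one seed.

## 2. State submodels

**Energetics.** Intake follows a Michaelis–Menten functional response
X = aV/(b+V) with a = 61.3 g·day⁻¹ per kg body mass and b = 40 g·m⁻² (the
biomass at which intake halves). A 4 h step converts
X · body_mass · 4/24 grams at 7.79 kJ/g. Costs sum a basal metabolic rate
per step, a linear cost of distance, and a linear cost of ascent;
descending is free (max(0, Δalt): the altitude difference enters without a
sign convention in the field's energetic bookkeeping, and charging descents
would double-count effort). No published point estimates are bundled
for the three cost coefficients; the defaults
(bmr_per_step = 1500 kJ per 4 h for a 100 kg animal, c_dist = 0.2 kJ/m,
c_climb = 2.7 kJ/m) are order-of-magnitude values from standard allometry
(Kleiber scaling; ~2 J·kg⁻¹·m⁻¹ horizontal, ~27 J·kg⁻¹·m⁻¹ vertical) and
are tagged `"appendix"` in `config_provenance()` so users with the original
coefficients can drop them in. Body mass itself (100 kg, an adult female)
is a package decision — intake is defined per kg of body mass, and the
reference mass is configurable.

**Memory.** The agent remembers up to `k_mem = 15` location clusters, each
a running-mean centroid with a member count. A new location within 1600 m
of a centroid joins that cluster (centroid moves to the running mean, count
increments, the cluster is refreshed as most recent); two *consecutive*
locations that fall outside every cluster but within 1600 m of each other
found a new cluster at their midpoint, evicting the oldest cluster at
capacity. The founding rule (`m_consec = 2`) and the capacity are package
decisions, and both are config values: the qualitative behaviour (clusters
form when consecutive locations are close; the oldest are deleted at
capacity) is fixed, the thresholds are not. The in-patch predicate is simply "within 1600 m of some centroid".

**Disturbance.** Proximity to roads and cutblocks influences step
*direction*: the covariate is cos θ × f(D) with f(D) = max(0, 1 − D/D₀)
and zero-crossings D₀ = 1500 m (roads), 1600 m (recent cuts), 1300 m
(regenerating cuts). D and the direction to the nearest feature are
measured from the step's start point — shared by all candidates of a
stratum, so the term differentiates candidates purely through their
bearing, which is the kernel's job: direction matters a lot near a
disturbance and not at all far from one. Measuring from the end
point would also have been defensible; it would add a small distance signal
to the term. If no feature of a kind exists, D = ∞ and the term is 0;
inside a feature cell, D = 0 and cos θ := 1 (the direction is undefined at
zero distance).

## 3. Replay: reconstructing the latent covariates

G, ΔE and the memory terms cannot be measured in the field; the replay
engine reconstructs them by walking each observed track through the same
submodels the simulator uses. For every observed step with a defined
previous heading, a stratum of 1 observed + 20 random candidates is
recorded with all covariates evaluated at the current state; then — and
only then — the *observed* step mutates state (feed, deplete, ledger,
memory, heading). Random candidates never touch state. ΔE used in the
interaction covariates is the ledger sum *before* the step's feed (the
state at decision time), scaled by `delta_e_scale = 10⁻³` so the
interaction covariates are numerically comparable to the others (ΔE in kJ
reaches ±5 × 10⁴; unscaled interactions would dominate exp(β·x) and make
fitted coefficients awkwardly tiny — a pure reparameterisation that only
changes coefficient units).

Two boundary choices: random candidates whose end leaves the map are
redrawn (up to 100 times) rather than clipped, preserving 20 valid controls
per stratum; and the first step of each track segment seeds the heading and
applies its feed/ledger/memory updates but forms no stratum (it has no
turning angle). Because such warm-up steps feed, the grams accounted in the
covariate table are the total removed from the grid minus the warm-up
feeds; `replay_track()` returns `total_ingested_g` so the mass balance can
be checked exactly, and the test suite does.

## 4. Estimation

The conditional likelihood
$\ell(\beta) = \sum_s [\beta^\top x_{obs,s} - \log \sum_{j \in s} \exp(\beta^\top x_j)]$
is maximised by Newton–Raphson with step-halving, convergence when the
log-likelihood moves by < 10⁻⁸, at most 100 iterations. Covariates constant
within every stratum leave the likelihood flat and raise an error rather
than returning an arbitrary coefficient; suspiciously large coefficients
(|β| > 30) trigger a separation warning. The naive covariance is the
inverse observed information.

**Dependence.** Consecutive 4 h steps are autocorrelated; deviance-residual
autocorrelation in this protocol dies out beyond lag 2 (8 h), so strata
are grouped into independence clusters: per individual, blocks of
`block_len = 24` consecutive strata (4 days; the block length is a config
value — only the gap and merge rules are pinned by the protocol) separated by 2 dropped
strata (8 h); simultaneous strata of individuals within 100 m merge their
blocks via union-find. The sandwich covariance is A⁻¹BA⁻¹ with B the sum of
outer products of cluster score sums; QIC = −2ℓ + 2 tr(A·V_r), which
reduces to AIC when clusters are singletons and the model is correct. QIC
weights are Akaike-style. Three nested candidates are compared: memory
(`cos_t_mem`), energetic (+ `g_over_l`, `gl_x_de` — the natural nesting for
a 3-parameter energetic model), environment (all ten terms). Coefficients
are reported unscaled, with no covariate standardisation.

**Cross-validation.** The case-control k-fold scheme refits on 80% of
randomly selected strata and ranks each held-out observed step among its 21
rows by score (1 = lowest). Ranks are tallied into 21 bins and Spearman's
r_s computed between bin index and frequency; the 80/20 split is drawn
fresh at random for each of the (default 100) repetitions rather than
cycling through a fixed 5-way partition of the strata. Ties
in scores get midranks, and a half-integer rank splits its unit mass
between the neighbouring bins; midranks are the standard tie treatment and
keep the oracle-scorer maximum analytic. A null
r_s per repetition uses uniformly random ranks.

## 5. Validation and scenarios

Home ranges are 95% minimum convex polygons: drop the ⌊0.05 n⌋ locations
farthest from the centroid, convex hull, shoelace area. RSFs contrast used
locations with uniform available points (10 per used point by default; the density is a
config value) inside the availability polygon, by
plain logistic regression on landcover presence/absence dummies with open
conifer without lichen (class 9) as reference. A GLMM with individual/year random
effects is the common alternative here; this package deliberately uses
fixed-effects logistic regression per individual/run and nonparametric
rank tests across runs — mixed-model machinery is out of scope, and the
quantities compared downstream (β-vector correlations, per-class
Wilcoxon-Mann-Whitney contrasts, Kruskal-Wallis style comparisons) only
need per-fit coefficient vectors. Complete separation (a class entirely
used or entirely available) is flagged and the coefficient excluded from
correlations rather than propagating a divergent estimate.

The encroachment scenario tiles the extent into 225 km² quadrats (600 × 600
cells at 25 m) and converts a centred square of 70% of each quadrat's area
to mixed/deciduous forest, skipping fixed open areas and water; lichen and
cover are re-derived from the class table for converted cells. Rounding the
square's side to whole cells makes the realised fraction 70.0% ± one cell
ring (the package tests require agreement within 1 percentage point).

## 6. Synthetic data: what it does and does not emulate

`synth_landscape()` draws a landcover mosaic by sampling classes at a
coarse block scale (expected patch ≈ 25 cells) from a requested mixture and
disaggregating to 25 m cells, adds straight-line roads, rectangular cut
blocks and a smoothed-noise DEM, and keeps feature masks consistent with
class codes. `synth_tracks()` produces gamma/wrapped-normal correlated
random walks at the fix interval. `synth_strata()` draws covariates i.i.d.
N(0, 1) and samples the case proportional to exp(β·x) — the exact
conditional-logit generative model used for estimator calibration.

These generators reproduce the *structure* the methods need (spatial
autocorrelation of classes, linear features, 4 h fix cadence, stratified
case-control sampling) but not the textures of real data: no GPS error or
missed fixes beyond what tests construct, no seasonal vegetation dynamics,
blocky patch boundaries, isotropic roads, and track generators with no true
habitat preference unless driven through the simulator. Green tests
therefore certify the estimators, the bookkeeping and the coupling — not
that any particular ecological parameter value is right for a real herd.

## 7. Numerical choices and degenerate inputs

* Angles are mathematical radians, turning angles wrapped to (−π, π]; the
  bearing convention is counter-clockwise from +x.
* Cells are half-open 25 m footprints, row-major with row 1 at the north
  edge (ESRI ASCII order); a point on a shared edge belongs to exactly one
  cell.
* The edge operator is the normalised Sobel gradient (central differences
  smoothed (1,2,1)/4 across the perpendicular axis) — the canonical
  3×3-Moore-neighbourhood gradient; borders use one-sided differences, a
  1×1 grid returns 0.
* The conditional likelihood uses per-stratum log-sum-exp guarding;
  `best` ties are broken by a seeded shuffle before argmax.
* Nearest-feature queries scan the (sparse) feature cell list exactly
  rather than precomputing a distance-transform raster; at package problem
  sizes the scan is faster than maintaining per-year transforms and is
  exactly Euclidean. Swapping in a transform would be an internal change
  only.
* Gap handling in tracks: a fix interval off by more than 10% of 4 h is a
  gap; no step spans it and the turning-angle chain restarts after it.
* Degenerate cases that return flagged results rather than errors:
  collinear/coincident MCP inputs (area 0), absent feature kinds (term 0),
  empty memory (cos θ_mem = 0), confinement rejection exhausting its cap
  (shortest draw retained, flagged).

## 8. Problem sizes

The shipped tests and demonstrations run on deliberately small instances
chosen to exercise every code path with tight statistical checks:
landscapes of 100–600² cells, 2–4 individuals, 40–220 steps, 50–500 strata,
20–100 cross-validation repetitions, 50-replicate calibration loops, and
10⁵-draw selection-rule checks. One full winter season is 648 steps
(108 days × 6), derived from the window dates rather than stored as a
constant; `run_pipeline()` accepts that size directly when a full-season
run is wanted.

## 9. Known limitations

Individuals interact only through depletion (no grouping or predator
agents); vegetation does not regrow within a run; the RSF layer is
fixed-effects only; raster IO is ESRI ASCII grid (no GeoTIFF reader is
bundled); per-class lichen biomass defaults are synthetic placeholders to
be replaced with survey estimates; and k-fold cross-validation inherits its
usual caveat that homogeneous environments make held-out data easy —
emergent-pattern validation (RSF correlations, home-range indices,
scenario contrasts) is the complementary, stricter check.
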