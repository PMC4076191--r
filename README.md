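# ssfwalk

Coupled statistical and individual-based modelling of large-herbivore
movement: step-selection functions (SSF) with latent internal-state
covariates, and a biased correlated random walk (BCRW) simulator driven by
the fitted SSF.

## The problem

Winter movements of woodland caribou in managed boreal forest reflect a
trade-off between the costs and benefits of moving: energy gained from
terrestrial lichen, energy spent on locomotion, the pull of remembered
forage patches, and avoidance of roads and cutblocks. Two of the drivers —
the animal's recent energy balance and its spatial memory — are internal
states that no collar measures. `ssfwalk` implements the coupled solution:
**replay** the observed GPS tracks through explicit energetics and memory
submodels to reconstruct those latent covariates step by step, fit the SSF
on the resulting table by conditional logistic regression (forward
modelling), and then use the same submodels plus the fitted SSF as the
movement trait of an individual-based simulation whose emergent patterns
(habitat selection, home ranges, responses to landscape change) can be
validated against the real system.

## The model

Each observed 4 h step is paired with 20 random steps sharing its start
point, drawn from the pooled empirical step-length and turning-angle
distributions. The SSF score of a candidate step with covariate vector
**x** is

    w(x) = exp(β₁x₁ + … + βₚxₚ)

and β is estimated by maximising the stratified conditional likelihood
(Newton–Raphson), with a cluster-robust sandwich covariance over blocks of
autocorrelated strata and QIC = −2ℓ + 2·tr(A·V_r) for model selection among
three nested candidates (memory / energetic / environment). The covariates
include cos θ_mem (alignment with remembered patch clusters), the
gain/loss ratio G/L from a Michaelis–Menten intake model
(X = aV/(b+V), a = 61.3 g·day⁻¹·kg⁻¹, b = 40 g·m⁻²; gains at
7.79 kJ/g), canopy cover, altitude, a 3×3 canopy-gradient edge term,
cos θ·f(D) disturbance terms with linear kernels vanishing at 1500/1600/
1300 m (roads, recent cuts, regenerating cuts), and interactions with the
72 h energy balance ΔE.

The simulator runs the loop forward: draw 21 candidate steps, score them
with the fitted SSF, select one (`best`, `best90`, `roulette` wheel on
w/(1+w), softmax `ssf`, or uniform `crw`), move, feed (depleting the cell's
lichen), update the energy ledger, memory clusters and heading — each
individual in series, everything reproducible under one seed. Validation
tools include case-control k-fold cross-validation with 21 rank bins and a
Spearman r_s statistic, 95% minimum-convex-polygon home ranges, RSF
β-vector comparisons between real and simulated individuals, and a
hardwood-encroachment scenario transform (70% of each 225 km² quadrat
converted to mixed/deciduous forest).

## Worked example

Everything below is synthetic and seeded; `run_pipeline()` builds a
landscape, generates reference tracks, replays them, fits and selects the
SSF, cross-validates, and simulates:

```r
library(ssfwalk)
pl <- run_pipeline(seed = 42, nrows = 150, ncols = 150,
                   n_individuals = 4, n_steps = 150,
                   cv_reps = 20, n_sim_runs = 3)
pl
#> <ssf_pipeline> seed 42 - 596 strata; selected model: environment
#>   model           K loglik   qic  dqic    weight converged
#> 1 environment    10 -1355. 2724.    0  1   e+  0 TRUE
#> 2 energetic       3 -1522. 3048.  324. 4.96e- 71 TRUE
#> 3 memory          1 -1686. 3372.  648. 1.57e-141 TRUE
```

The full model wins decisively (ΔQIC ≥ 324): the latent energetic and
memory covariates carry real signal. Its coefficients, in broom shape:

```r
tidy(pl$fit)
#>    term       estimate std_error robust_se ...
#>  1 cos_t_mem   0.348      0.095    0.072        # pull toward known patches
#>  2 g_over_l    0.492      0.238    0.151        # selection for energy-profitable steps
#>  3 cover      -0.0172     0.015    0.0067       # open stands preferred
#>  6 road_term  -0.335      0.147    0.128        # roads avoided when close
#> 10 cover_x_de -0.000616   0.00019  0.0001       # cover avoidance grows with energy
```

Cross-validation ranks each held-out observed step among its 21 candidates:

```r
pl$cv
#> <ssf_cv> environment model, 20 reps, 21 rank bins
#>   r_s = 0.911 (95% CI 0.808 to 0.959); null r_s = -0.057 (-0.311 to 0.283)
```

A mean rank–frequency correlation of 0.91 against a null near zero means
the fitted SSF concentrates observed steps in the top bins. Home-range
sizes of SSF-driven simulations are then compared through a symmetric
index (0 = equal areas, +1 = simulated twice as large, −1 = half):

```r
pl$validation$homerange_index
#> [1] -2.33 -4.56 -7.19     # exploitative selection shrinks ranges
```

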