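---
title: "Models and methods in rangecomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rangecomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

`rangecomp` studies how group size and climate variability jointly shape
resource competition in group-living animals — the motivating system is a
population of 10–13 neighbouring white-faced capuchin groups (5–40
individuals, population mean near 19) tracked for about three decades in a
highly seasonal tropical dry forest, where dry-season water, food and shade
concentrate in evergreen riparian zones and interannual anomalies are
ENSO-linked. Within-group competition predicts that larger groups eat less
per capita, travel or range more, and revisit less; between-group competition
predicts that relatively larger groups encroach on smaller neighbours and
claim greener ranges when resources contract.

Because the field data behind such studies are restricted, the package is
built around a synthetic study system with known ground truth
(`default_truth()`): every downstream quantity — spatial metric or posterior
— can be checked against the parameters that generated the data. The
package's claims are therefore *methodological*: the metrics agree with
closed-form geometry, and the models recover what the generator encoded, at
field-realistic scales.

## The synthetic study system

`gen_demography()` draws yearly group sizes as bounded integer random walks
(bounds 5–40, initial mean 18.8, step sd 1.4), split into dry (January–April)
and wet (May–December) season records. `gen_climate()` produces one
water-balance anomaly per season-year from an AR(1) process (coefficient 0.6,
matching the multi-season persistence of ENSO-linked drought indices) and
standardizes it within season, so `spei_z` measures departure from typical
conditions *for that season*.

`gen_landscape()` builds a 200 × 200-cell grid at 30 m — Landsat resolution —
crossed by a sinuous river. True dry-season NDVI decays with distance to the
river (`0.22 + 0.45 exp(-d/350 m)`); wet-season NDVI is high and spatially
flat. Satellite images add sensor noise, a strictly downward haze bias, and a
random cloud mask (12% of cells), which is why the pixel-wise **maximum**
composite is the right seasonal summary; the package implements maximum
composites throughout (the alternative median composite would estimate the
haze-shifted centre rather than the clear-sky value).

`gen_space_use()` gives each group-season an isotropic Gaussian utilization
distribution (UD). The 95% home-range area follows
`log(area) = log(1.6e6) + 0.3 size_z + 0.25 wet + N(0, 0.18)` (m²), so
larger groups hold larger ranges by construction. Dry-season range centres
are pulled toward the river with strength
`0.45 · size_z · (1 + (2/3) spei_z)` on the log-distance scale: larger groups
claim riparian (greener) cells, most strongly in abnormally *wet* dry seasons
and not at all at `spei_z = −1.5`. This placement rule is what makes the
dry-season size → range-NDVI slope positive at anomaly +1.5 and near zero at
−1.5 in the fitted beta model. Movement is a stationary Ornstein–Uhlenbeck
process (30-min crossing time, 5-min fixes, 11.5-h days); Gaussian mixtures
with more components are supported in configuration but the single-component
default keeps every encounter-rate and contour oracle closed-form.

`gen_foraging()` draws focal bite counts from a negative binomial with a
`log(seconds-in-view)` offset; the size slope is −0.2 with anomaly modifiers
(+0.133 dry, −0.133 wet per anomaly sd) chosen so the size cost vanishes
under counterbalancing anomalies and roughly doubles under reinforcing ones —
the pattern the three-way interaction in the intake GLMM estimates.

`gen_srm_data()` and `gen_encounter_data()` draw the dyadic outcomes directly
from the dyadic models described below with known coefficients. The pipeline
deliberately fits its dyadic models to these *model-generated* outcomes (the
geometric overlap/encounter tables are validated separately against analytic
oracles): that is the only design in which "does the model recover the truth"
is a well-posed question for every coefficient. The number of dyads observed
per period is configurable rather than fixed, since no canonical empirical
distribution exists for it.

All layers fan a single master seed into independent substreams by stable
string hashing (`substream_seed()`), so any layer is reproducible in
isolation and identical (config, seed) pairs are byte-identical end to end.

## Spatial estimation

**UDs.** `fit_ud()` is a plug-in-bandwidth Gaussian kernel density on the
shared grid, renormalized to integrate to exactly 1, with per-axis Silverman
bandwidth `min(sd, IQR/1.34) · n^{-1/6}`. Autocorrelated KDE with
continuous-time model selection is intentionally *not* re-implemented: the
downstream contract is only a normalized probability surface, simplified
ranges are known to align closely with conventional UDs in this system, and
the plug-in KDE admits exact Gaussian oracles (a 95% contour of an isotropic
Gaussian must have area `π σ² χ²₂(0.95)`; the test suite requires agreement
within 5%, the small positive bias being kernel smoothing of order
`(h/σ)² ≈ n^{-1/3}`).

**Home ranges.** `hr_contour()` takes the highest-density cell set reaching
the target mass; area is **cell mass** (cells × cell area), not a smoothed
polygon, which keeps the production rule and the brute-force sorted-cell
oracle identical by construction. 95% is the convention for tracking-era
ranges and 98% for sleep-site ranges (both exposed). Area SEs come from a
point bootstrap refitting the UD.

**Daily path length** is mean speed × duration, with mean speed the summed
step length over duration at the native interval, an SE from a moving-block
bootstrap (30-min blocks), and days under 11 tracked hours flagged out. This
estimator is subsampling-stable only for paths smooth at the fix interval —
the tests document this property on a smooth track and the pipeline always
uses the native resolution.

**Revisitation** is the UD-weighted mean of speed × UD:
`radius · speed · ∫ p(x)² dx`, exactly linear in the radius (25–50 m are
typical reporting scales). For a Gaussian UD `∫p² = 1/(4πσ²)`, giving the
package's 1%-level oracle and the structural reason revisitation falls with
range area (hence with group size) in the fitted models. Absolute values are
comparable within the package, not to other implementations' internal radial
scalings.

**Dyadic metrics.** Directed proportional overlap is `PO_fn = IA_fn / HRA_f`
on the contour cell sets (the intersection area is exactly symmetric; the
ratio is not — it reads as neighbour encroachment onto the focal range), and
every unordered pair-period appears twice with swapped roles. The encounter
rate is the UD product integral `area_scale · ∫ p_i p_j dx` (default scale
1 m²), symmetric bit-for-bit under argument swap and checked against the
closed form `N(μ_i − μ_j; 0, Σ_i + Σ_j)` within 1%.

**Range-shift attribution.** Qualifying events need a directed overlap
rising from below 0.25 to above 0.45 (strict comparisons, exactly as those
thresholds are printed) with a net relative-size change of at least 5
individuals, over all forward period pairs in a dyad; `delta_d` is
`D_{t+i} − D_t`, the change in distance from a group's period-t centroid to
the overlap centroid, taken literally with this sign. The driver is the group
with the larger |ΔD|; exact ties are labelled indeterminate and excluded
from the driver proportion. A geometric caveat the tests exposed and the
package documents: when the two range centroids and the overlap centroid are
collinear, |ΔD| is *identical* for both groups for any overlap displacement
(both are distances to the same two points from opposite sides), so the
classification resolves only configurations where the approach is oblique or
range shapes are asymmetric. The packaged oblique-expansion scenario is
attributed to the expander in 100% of replicates, and the attribution
sharpens monotonically with expansion strength; on the symmetric default
scenario the driver proportion sits only modestly above one half, which is
the honest consequence of Gaussian range symmetry rather than a failure of
the bookkeeping.

## The Bayesian models

All inference runs in JAGS (4 chains × 1000/1000/1000 by default; reduced,
clearly stated budgets for calibration studies and pipeline runs), with
convergence gated at split R̂ < 1.01 — violations are *flagged*, not hidden;
under reduced budgets the flags typically point at varying-effect standard
deviations, whose slow mixing is expected with 12 groups, while the fixed
effects and contrasts the analyses report mix an order of magnitude better.

**Group GLMMs** (`fit_group_glmm()`): negative binomial (mean–dispersion)
for intake with the log observation-time offset; gamma (mean–shape, log
link) for path length, revisitation and range area; beta (mean–precision,
logit link) for range NDVI, with boundary observations nudged inward by 1e-6
and counted. Fixed effects are `size_z`, season, their interaction and
optionally the full three-way interaction with `spei_z`; varying intercepts
by group, plus individual (intake) or year (NDVI). Measurement error on a
response enters as a Gaussian on the log (link) scale with known per-row SE
around a latent gamma-distributed truth. `marginal_slope()` evaluates the
per-draw size slope at a season and anomaly value ({−1.5, 0, +1.5} are the
reporting conventions); `seasonal_contrast()` gives per-draw wet − dry
differences. Summaries are posterior medians, 89% HPDIs (`hpdi()`, shortest
sorted-sample interval) and PP > 0.

**Hurdle-beta social relations model** (`fit_srm()`): the directed overlap
likelihood separates zero overlap (Bernoulli, logit link) from its degree
when present (beta, logit mean, log precision). Both branches carry
intercept, focal size, neighbour size and their product (plus a wet-season
term in seasonal specs). Varying effects follow the canonical SRM covariance:
per-group focal and neighbour effects bivariate normal with correlation
`ρ_gr`, per-dyad directed effects with within-dyad correlation `ρ_dd`,
implemented through the exact conditional factorization of the bivariate
normal (numerically safer than inverting near-singular 2 × 2 covariances)
with a `(1 − ρ²)`-shaped prior on correlations (the 2 × 2 LKJ(2) density)
and half-Normal(0,1) SDs. The two branches share one set of realized varying
effects with branch-specific fixed effects — the package's main structural
assumption, stated here because published SRM variants differ in exactly
this sharing; it matches the generator, and a toggle-free single default
keeps calibration interpretable. `conditional_neighbour_slope()` evaluates
the neighbour-size slope at focal sizes {8, 21, 35}, z-scored with the scale
stored on the fit.

**Multiple-membership encounter model** (`fit_encounter_mm()`): Gaussian on
log encounter rate with the known per-row measurement SE marginalized into
the observation variance; fixed effects are the three symmetric predictors
(|size difference|, log overlap area, overlap greenness, each z-scored
internally) and their season interactions; varying effects are a dyad
intercept and a group term loading on *both* members with weight 1. The
linear predictor sums the two group effects inside one bracketed term, so
the posterior is invariant — bit for bit at a fixed seed — under swapping
the group labels within rows.

**Priors** are weakly regularizing: Normal(0, 1) on standardized-scale
slopes, Normal(0, 5) on intercepts, half-Normal(0, 1) on varying-effect SDs,
and Normal(0, 2.5) on log shape/precision/dispersion parameters. The wider
intercept and auxiliary-scale priors are deliberate: intercepts on
offset/exposure scales (log bites per second ≈ −4.8, log encounter rate ≈
−6) and beta precisions in the hundreds sit far outside a unit-scale prior,
which would otherwise shrink them enough to distort calibration.

**Identification of intercepts.** With unconstrained varying intercepts the
model intercept and the mean of the realized effects are additively
confounded, which stalls naive MCMC. The package samples the unconstrained
model (fast, and what the block samplers handle well) while monitoring the
varying-effect means as cheap deterministic nodes, then recovers the
identified intercept per draw by sweeping those means into it before
diagnostics ("post-sweeping"). A related finite-sample fact shapes the
calibration design below: a fitted intercept estimates the truth *plus the
realized mean* of that replicate's group and dyad effects, a quantity that
varies across replicates by roughly `sd/√n_groups` — so interval coverage of
the configured intercept is not a meaningful check, and calibration targets
slopes, interactions and contrasts.

## Calibration design and what passing shows

Three layers of evidence, in increasing strength:

1. **Analytic oracles** (exact or 0.5–5% tolerances): two-disc lens overlap,
   Gaussian product-integral encounter rates, χ² contour areas, Gaussian
   self-overlap revisitation, hurdle-beta density identities and total mass.
2. **Direct estimator recovery** on generator output: OLS on log true areas,
   quasi-likelihood intake regression, sample correlations of dyad effects —
   each generative coefficient is recoverable by a matching non-Bayesian
   estimator at large n.
3. **Simulation-based calibration** at study scale: 20 replicates per model
   family (intake NB with the three-way interaction; hurdle-beta SRM; the
   encounter model), requiring every slope's 89% HPDI to cover its truth in
   at least 70% of replicates (the binomial tolerance at 20 replicates), plus
   structure recovery — `ρ_dd = 0.8` recovered with posterior median in
   (0.5, 0.95) on a 15-group × 10-period dataset, and the conditional
   neighbour-slope ordering across focal sizes matching the negative
   interaction.

Replicate sizes (8–12 groups, 4–8 years, a few hundred to ~500 rows per
fit; pipeline fits up to ~2000 rows) and reduced MCMC budgets were chosen
once as the smallest sizes at which the direct estimators in layer 2 are
stable, and then fixed. Passing these tests shows the machinery is correct
and calibrated *for data with this structure*; it does not show that real
capuchin ranges are Gaussian, that real overlap follows a hurdle-beta law,
or that NDVI measures food. The generator omits, among other things:
location error, irregular sampling, range-resident autocorrelation beyond
OU, resource-selection weighting of UDs (tree-cover "soft barriers"),
fission spatial inheritance, and observation effort that varies with group.

## Numerical choices and degenerate inputs

Grid convention: cell-centre coordinates, metres, origin at the lower-left
corner; zonal means use the cell-centre-in-polygon rule with no partial-cell
weighting. Missing values propagate through all raster arithmetic;
composites skip them. Coincident points (zero bandwidth), empty seasonal
image windows, single-year climate series, non-double-entered dyad tables,
non-positive measurement SEs and zero-area focal ranges are rejected with
informative errors; group-seasons with missing sizes are skipped with a
warning; groups appearing in fewer than two dyads trigger a
weak-identification warning rather than rejection. Proportions at exactly 1
are shrunk by 1e-9 in the hurdle-beta density (counted); beta responses at 0
or 1 are nudged by 1e-6 (counted). Raster I/O uses the plain-text ESRI ASCII
grid format; ranges export as GeoJSON in local metric coordinates.

## Known limitations

The default UDs are single Gaussians, so range asymmetry effects (e.g. on
driver attribution) are underrepresented; the driver-proportion statistic is
reported with its exact binomial CI but not compared against any field
value. Variance-component posteriors mix slowly at reduced MCMC budgets and
are flagged by the R̂ gate. The pipeline's geometric encounter table carries
no SE by default (the bootstrap is available but costly); model fits of
encounter rates therefore use the generator's outcomes, where the
measurement-error design is exact. The 6-month anomaly accumulation is
consumed as an external series, not recomputed from climate inputs.
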