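# rangecomp

Tools for asking how **group size** and **climate variability** jointly shape
within- and between-group resource competition in group-living animals —
motivated by long-term studies of neighbouring white-faced capuchin groups
(5–40 individuals) on a seasonal riparian landscape, where dry-season
resources contract into green river corridors and interannual anomalies are
ENSO-linked.

The package provides, as a tested pipeline over a synthetic study system with
known ground truth:

- **Synthetic study system** (`gen_demography()`, `gen_climate()`,
  `gen_landscape()`, `gen_space_use()`, `gen_foraging()`, `gen_srm_data()`,
  `gen_encounter_data()`): three decades of group sizes, seasonal
  water-balance anomalies (AR(1), standardized within season), RED/NIR
  imagery with cloud masks over a riparian greenness gradient,
  Ornstein–Uhlenbeck trajectories around Gaussian utilization distributions,
  negative-binomial focal bite counts, and dyadic outcomes drawn from the
  dyadic models themselves — every effect recoverable against configured
  truth.
- **Environment**: NDVI = (NIR − RED)/(NIR + RED) with QA masking
  (`compute_ndvi()`), pixel-wise maximum seasonal composites
  (`seasonal_composite()`), within-season anomaly standardization
  (`standardize_spei()`), and exact cell-centre zonal means
  (`mean_raster_in_range()`).
- **Space use**: plug-in-bandwidth kernel UDs normalized on a shared grid
  (`fit_ud()`), highest-density home-range contours with cell-mass areas and
  bootstrap SEs (`hr_contour()`), daily path lengths (speed × duration with
  block-bootstrap SEs, `daily_path_length()`), and revisitation rates
  `radius · speed · ∫p²` (`revisitation_rate()`).
- **Dyadic metrics**: directed proportional overlap `PO_fn = IA_fn / HRA_f`
  (`proportional_overlap()`), overlap zones with mean greenness
  (`overlap_zone()`), symmetric encounter rates
  `ER = area_scale · ∫ p_i p_j dx` (`encounter_rate()`), and range-shift
  events (overlap < 0.25 rising to > 0.45 with net relative-size change ≥ 5)
  with centroid-shift driver attribution (`select_shift_events()`,
  `classify_driver()`, `driver_proportion()`).
- **Bayesian models** (JAGS): group-level GLMMs — negative binomial with a
  log observation-time offset for intake, gamma (optionally with known
  measurement error on the log response) for path length / range area /
  revisitation, beta for range NDVI — with size × season × anomaly
  interactions (`fit_group_glmm()`, `marginal_slope()`,
  `seasonal_contrast()`); a **hurdle-beta social relations model** for
  directed overlap with correlated focal/neighbour/dyad varying effects
  (`fit_srm()`, `conditional_neighbour_slope()`); and a **symmetric
  multiple-membership model** for log encounter rates with known per-row SEs
  (`fit_encounter_mm()`, `season_slope_contrast()`). Summaries are posterior
  medians, 89% HPDIs and PP > 0.

## Worked example

```r
library(rangecomp)

res <- run_pipeline(run_config(seed = 1))   # ~10 min on one CPU
res$summary$headline
```

The default scenario simulates 12 groups over 1994–2023, estimates every
spatial metric from the trajectories, fits all seven models, and checks each
recovered headline effect against the sign of the generative truth. The same
stages run as a narrated workflow through the numbered scripts
(`Rscript analysis/01_simulate.R` … `analysis/07_report.R` from the
repository root), which write tables, rasters and figures under `results/`.
The seed-1 report prints:

```
headline effects (posterior median [89% HPDI], truth sign):
  size_to_intake                     -0.134 [-0.210, -0.066]  truth -1  ok
  size_to_hra                        +0.303 [+0.275, +0.336]  truth +1  ok
  size_to_revisitation               -0.150 [-0.174, -0.132]  truth -1  ok
  neighbour_size_to_po_small_focal   +0.873 [+0.790, +0.955]  truth +1  ok
  wet_minus_dry[overlap_area]        -0.473 [-0.506, -0.442]  truth -1  ok
  size_to_ndvi_dry_wet_anomaly       +0.185 [+0.163, +0.213]  truth +1  ok

sign agreement: 6 / 6
shift drivers: became-larger group in 60% of 120 events
```

Reading the rows: larger groups ingest fewer bites per second in view
(negative size slope on the log scale) and revisit previously used areas
less, but hold larger ranges (log-area slope 0.30; configured truth 0.3);
neighbour size increases directed overlap most strongly when the focal group
is small; the overlap-area effect on encounter rate is stronger in the dry
season (negative wet − dry contrast); and in wet-anomaly dry seasons larger
groups sit on greener ranges. The conditional-slope tables show the full
anomaly dependence — e.g. the dry-season intake slope runs from −0.33 at
anomaly −1.5 through −0.09 at 0 to +0.14 at +1.5 — and
`conditional_neighbour_slope()` gives the overlap slope by focal size
(+0.87 at 8, +0.27 at 21, −0.39 at 35 animals).

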