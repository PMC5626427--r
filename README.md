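# octsector

Structural progression of glaucoma — especially normal-tension glaucoma,
where intraocular pressure is a poor biomarker — is increasingly followed
with OCT measurements of the macula. `octsector` implements an
*axonal-tract-dependent* sectorization of the fovea-centered 10×10 macular
thickness grid and uses the resulting sectors to detect longitudinal
progression in the macular retinal nerve fiber layer (mRNFL) and the
ganglion cell + inner plexiform layer (mGCIPL). It is aimed at researchers
analysing longitudinal OCT + visual-field cohorts and at methodologists who
need a fully synthetic, ground-truthed test bed for progression detection
rules.

## What it computes

**Sectorization.** For each grid point *g* and each temporal circumpapillary
clock sector *s* ∈ {7, …, 11} (right-eye convention), the Spearman rank
correlation ρ(g, s) between macular thickness at *g* and circumpapillary
RNFL thickness in *s* across eyes. A point is assigned to
argmax<sub>s</sub> ρ(g, s) when max ρ ≥ 0.4 and p < 0.05, then the raw map
is cleaned against a parametric arcuate model of nerve-fiber trajectories
(4-connected sectors, no labels across the horizontal raphe).

**Trend analysis.** Per eye (≥ 5 visits over ≥ 2 years) and region
(average, hemifields, clock sectors), the OLS slope β (µm/year) of the
region-mean thickness, tested against a normative course by
*z* = (β − µ₀) / √(se² + σ₀²) with one-sided p < 0.05, where (µ₀, σ₀) are
the normative slope mean and between-subject SD. Per-eye selections
(`faster_hemifield`, `fastest_sector`, `fastest_overall`) are the most
negative slopes among the relevant regions.

**Event analysis.** A region has progressed when a visit falls below
baseline − k·σ<sub>f</sub>·√1.5 (baseline = mean of the first two exams,
σ<sub>f</sub> = test–retest fluctuation SD, k = 2) and the next visit
confirms it.

**Visual-field progression.** Pointwise OLS on the central 16 points of the
24-2 pattern; a point progresses when its slope is worse than −1 dB/year
(and significant); an eye is a progressor when ≥ 3 progressive points form
a 4-connected cluster.

**Synthetic cohorts.** `generate_cohort()` simulates eyes with
bundle-linked baseline damage, per-bundle progression slopes, OCT
measurement noise, and visual fields tied linearly to cumulative mGCIPL
loss — with full ground truth for every eye.

## Worked example

```r
library(octsector)

sim <- generate_cohort(cohort_config(), seed = 1)   # 122 eyes, 8 visits
sectors <- derive_sector_map(
  sim$cohort,
  bundle = bundle_model(superior_curvature = 0.6, inferior_curvature = 0.6))
sectors
#> mRNFL sector map (T left, S top; '.' unassigned):
#>   1 1 1 1 1 1 1 1 1 1
#>   1 1 1 1 1 1 1 0 0 0
#>   0 0 0 0 0 0 0 0 0 0
#>   0 0 0 0 0 0 0 0 0 0
#>   9 9 9 9 9 9 9 9 9 9
#>   9 9 9 9 9 9 9 9 9 9
#>   8 8 8 8 8 8 8 8 8 8
#>   8 8 8 8 8 8 8 8 8 8
#>   7 7 7 7 7 7 7 8 8 8
#>   7 7 7 7 7 7 7 7 7 7
```

The arc-shaped sectors (11 superior-temporal, 10 superior, 9 straddling the
raphe, 8 and 7 inferior) recover the generating bundle map. Trend analysis
then summarises per-region slopes:

```r
trend <- trend_analysis(sim$cohort, sectors)
dplyr::filter(glance(trend), layer == "mRNFL")
#>    region          n_eyes mean_slope sd_slope prop_progressive p_vs_average
#>  1 average            122     -0.253    0.342           0.115     NA
#>  2 superior           122     -0.228    0.403           0.115      3.38e- 1
#>  3 inferior           122     -0.277    0.422           0.0984     3.38e- 1
#>  4 faster_hemifield   122     -0.427    0.427           0.189      9.36e-22
#>  ...
#> 10 fastest_sector     122     -0.842    0.695           0.377      9.36e-22
```

The cohort-mean slope of the entire macula (−0.25 µm/year) is much slower
than the per-eye fastest sector (−0.84 µm/year, Wilcoxon signed-rank
p ≈ 1e-21 vs the average region): selecting the fastest-progressing
axonal-tract sector exposes focal loss that the whole-map average dilutes.
Event analysis and the visual-field classifier feed an agreement table:

```r
events <- event_analysis(sim$cohort, sectors)
vf <- vf_analysis(sim$cohort)
agreement(vf[c("eye_id", "vf_progressor")], event_labels(events))
#>   criterion             both vf_only oct_only neither     n
#> 5 mRNFL_any_sector         7       0       21      94   122
#> ...
```

`run_pipeline(cohort_config(), seed = 1, out_dir = "out")` chains all of
the above and writes tidy CSVs plus a JSON manifest;
`inst/scripts/octsector.R` exposes the same steps as shell subcommands.
`autoplot()` methods render the sector map and slope distributions.

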