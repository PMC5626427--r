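---
title: "Methods: axonal-tract-dependent macular sectors and progression detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axonal-tract-dependent macular sectors and progression detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsector)
```

## The problem

Glaucomatous damage follows the retinal nerve fiber bundles: macular grid
points served by the same bundle thin together, and their thickness co-varies
with the circumpapillary RNFL (cpRNFL) clock sector where that bundle enters
the optic disc. `octsector` operationalises this in three stages: (1) derive
a data-driven partition of the 10×10 macular grid into temporal clock
sectors (7–11 o'clock) from cross-sectional correlation; (2) detect
longitudinal progression per sector with a trend rule and an event rule;
(3) compare both against a pointwise-regression visual-field (VF)
classification on the central 16 points of the 24-2 pattern.

All grids are kept in a single internal frame: right-eye orientation, row 1
= superior retina, column 1 = temporal. Left eyes are mirrored on ingest
(columns flipped, clock hours reflected across the vertical meridian, VF
columns flipped), so one sector map serves both eyes; files on disk stay in
the eye's native orientation and round-trip exactly.

## Sector derivation

For each grid point and temporal clock sector, Spearman's rank correlation
is computed across eyes (one visit per eye — the first by default; pooling
visits would pseudo-replicate eyes). Rho is the Pearson correlation of
mid-ranks (average ranks on ties) and the p-value uses the large-sample t
approximation on n − 2 degrees of freedom. A constant input leaves rho
undefined; undefined correlations are flagged and treated as
"not correlated", never as zero.

A point is assigned to its argmax-rho sector when max rho ≥ 0.4 and
p < 0.05 (uncorrected across the 100 × 5 tests, matching per-point testing
practice; a Benjamini–Hochberg option exists and is off by default). Ties
break toward the sector predicted by the anatomical trajectory model, then
toward the lower clock hour.

### Anatomical trajectory model

Bundle trajectories are modelled parametrically: a grid point at signed
height $y$ above the raphe (row units) and normalized temporal distance
$d_t$ from the disc has entry height $h = y\,(1 + \kappa\, d_t)$, with
hemifield curvature $\kappa$ (default 0.8 per hemifield). Thresholding
$|h|$ yields arc-shaped sectors: a papillomacular band (|h| ≤ 1.2 → sector
9) straddling the raphe, sectors 10/8 for moderate |h| and 11/7 beyond 4.6.
The curvature term bends iso-sector contours temporally, reproducing the
arcuate geometry; by construction no trajectory crosses the horizontal
raphe. The functional form is a package design choice — anatomy motivates
the arcs but prescribes no equation.

### Anatomical correction

The raw argmax map is cleaned by deterministic conservative sweeps until a
fixed point: (a) raphe violations (an inferior-trajectory point carrying a
superior label, or vice versa) take their trajectory label; (b) a point with
no same-label 4-neighbour is absorbed by the majority hemifield-consistent
neighbour label; (c) all but the largest 4-connected component of each label
are relabeled (trajectory label, or neighbour majority, or unassigned when
no consistent label is reachable); (d) an unassigned point is filled with
its trajectory label when at least 3 assigned neighbours share it. The
procedure aborts with a diagnostic map if the invariants (4-connected
sectors, raphe consistency) are not met within 100 sweeps. A map that
already satisfies them is returned unchanged. Because the published
correction is described only as "anatomical reference", this algorithm is
original to the package; recovery tests run it with a curvature deliberately
different from the generator's (0.6 vs 0.8) so the check is not circular.

## Progression rules

**Trend.** Region-mean thickness is regressed on time (years of 365.25
days; origin = first visit) by OLS; the closed-form slope, SE and R² are
returned. Progression requires the slope to be significantly below the
normative course: $z = (\beta - \mu_0)/\sqrt{se^2 + \sigma_0^2}$, one-sided
p < 0.05, where $\mu_0, \sigma_0$ are the normative slope mean and
between-subject SD. Combining the sampling SE with the normative SD is a
package decision (no formula is published); under eyes drawn from the
normative population the rule holds its nominal 5% rate, which the test
suite checks by simulation. The bundled normative defaults
($\mu_0 = -0.1$, $\sigma_0 = 0.3$ µm/year, fluctuation SDs 0.6–0.8 µm) are
synthetic placeholders, clearly not estimates from any published normative
database, and should be replaced for real data.

**Event.** Baseline is the mean of the first two exams. A later exam is
flagged when it falls below baseline − k·σ_f·√1.5; the √1.5 corrects for
comparing one exam against a two-exam mean
(Var[x − (b₁+b₂)/2] = σ²(1 + ½)). k defaults to 2. A flagged exam must be
followed by `confirm` (default 1) consecutive flagged exams; the onset is
the first exam of the confirmed run. The final visit cannot confirm itself
unless `confirm_at_end = TRUE` — an unconfirmable terminal dip is treated as
pending, not progression.

**Per-eye selections.** `faster_hemifield`, `fastest_sector` and
`fastest_overall` are argmins over estimated slopes (ties to the lower
clock hour, superior before inferior). They are reported without
selection-bias correction — deliberately, because the comparison of
selected-vs-average slopes is itself the analysis of interest; the
selection effect is real and is what the sign-test property in the test
suite quantifies. The fastest sector is selected on the macular layer's own
slope (a published description mentions selection by cpRNFL slope while
reporting macular slopes; the macular reading keeps the table
self-consistent).

**Visual field.** Pointwise OLS of sensitivity on years over all exams
(baseline exams included). A point is progressive when its slope is worse
than −1 dB/year and (by default) p < 0.05 — the proprietary reference
software gates on significance, while the plain threshold is also quoted;
`require_significance = FALSE` gives the threshold-only reading. An eye is
a progressor when ≥ `min_points` progressive points form a 4-connected
cluster within the central 4×4 block. "More than 2 continuous points" is
read literally as ≥ 3; `min_points = 2` is available since conventions
differ.

## The synthetic cohort generator

The generator is the package's test bed and defines the study conditions:
122 eyes (roughly half of patients contributing both eyes), 8 visits at
~115-day intervals (≈ 2.2 years; at least 5 visits over 2 years are
required by the analyses), per-grid-point noise SD 2 µm plus a per-visit
common offset of 0.5 µm (test–retest OCT error has a shared
scan-alignment component), cpRNFL noise 4 µm, VF point noise 1.5 dB.

Each eye draws a severity in [0, 1] per bundle — a Beta(2, 2.45) mixture of
an eye-level and a bundle-level component (weight 0.3) so damage is
correlated within an eye but still separable across bundles — and a slope
per bundle: background N(−0.1, 0.2) µm/year, with 30% of eyes receiving 1–2
fast bundles at N(−1.5, 0.6) truncated at 0. Grid point thickness is
`template × (1 − susceptibility × severity) + slope × t + noise`, clipped
at 0 and 200 µm. Susceptibilities (mRNFL 0.92, mGCIPL 0.40) and the
severity scale were set so that cohort baselines sit at the
normal-vs-glaucoma gap of the healthy targets (≈ 21 vs 35 µm mRNFL average,
≈ 56 vs 68 µm mGCIPL); the slope scale puts the cohort-average trend near
−0.2 to −0.35 µm/year with fastest sectors near −1 µm/year. The mGCIPL
slope is 1.3 × the mRNFL slope of the same bundle. Temporal cpRNFL sectors
share their bundle's severity and 1.5 × its slope; non-temporal hours carry
the eye-mean severity and no trend.

VF sensitivity at a central-16 point equals a 30 dB normal minus
`vf_link` (0.8 dB/µm) times the cumulative mGCIPL loss at the structurally
mapped grid point (the field is vertically inverted on the retina), plus
noise; total deviation is sensitivity minus the normal. Ground truth
(per-bundle severity and slope, the generating sector map, the noise-free
VF progressor label) is returned alongside the cohort and is never consumed
by the analysis functions.

The healthy templates are smooth 10×10 surfaces anchored at per-sector
healthy target means, with a within-sector shape (an annulus peaking ~2.5
grid units from the fovea for mGCIPL; a disc-ward gradient for mRNFL) and a
final per-layer offset that makes the 100-point average match the average
target exactly. The sector targets over-determine the average, so sector
means carry a common offset (≈ +2.0 µm mRNFL, −0.7 µm mGCIPL under the
default geometry, whose sector sizes are 17/23/20/23/17 points for
7/8/9/10/11); orderings among sectors are preserved exactly.

What the generator does *not* emulate: OCT speckle and segmentation error,
perimetric staircase/response errors (VF noise is Gaussian), floor effects
beyond a hard clip, eye-level correlation between fellow eyes of one
patient, age drift in the healthy template, and media-opacity-driven
quality loss (quality scores are uniform draws, so the ingest quality
filter is exercised by I/O tests, not by the default cohort). Passing tests
therefore demonstrate correctness of the rules and recoverability under
idealised Gaussian conditions, not clinical performance.

Under the default noise and visit schedule the *measured* VF progressor
rate runs below the generating truth rate: with 8 exams over ~2.2 years a
true −1.5 dB/year point slope is near the edge of per-point significance,
so the significance gate attenuates classification. This mirrors the
known insensitivity of pointwise regression on short series and is left
as-is.

## Numerical and interface choices

- Dates are integer days from the first visit; slopes are per year
  (365.25 days). Degenerate inputs error early: < 5 visits or a single
  distinct date for OCT slopes, < 3 exams for VF slopes, < 2 exams for the
  event baseline, constant vectors for correlation (flagged NA).
- Quality filtering keeps visits with quality strictly above the threshold
  (default 40, the cohort inclusion rule; 70 — the stricter per-scan rule —
  is a parameter). Which threshold governed which published analysis is
  ambiguous, so both are exposed and the laxer one is the default.
- The event rule's k, the √1.5 baseline correction, and the confirmation
  policy are surfaced in the configuration because the published criterion
  ("significantly lower than the natural fluctuation level") fixes none of
  them.
- `faster_hemifield`/`fastest_sector` rows join the normative table under
  their own region ids with the same synthetic defaults; the z-test there
  inherits selection bias, as intended.
- All randomness flows from a single integer seed; identical configuration
  and seed give byte-identical output CSVs (`run_pipeline()` writes a JSON
  manifest with the seed and a configuration hash).
- Group comparisons use the Mann–Whitney test (exact for small untied
  samples; otherwise the tie-corrected normal approximation without
  continuity correction, which coincides with a two-group Kruskal–Wallis),
  Fisher's exact test for categorical variables, and Wilcoxon signed-rank
  for paired region-vs-average slope contrasts. Sex-ratio style comparisons
  between independent groups use Fisher's exact test (a paired test is
  sometimes quoted in this role but does not apply to independent groups).

## Problem sizes

The test suite and `scripts/acceptance.R` use: 120–200 eyes for sector
recovery and selection properties, 500 eyes for slope-estimator
calibration, 1000 null eyes for the trend rule's type-I rate, 2000 null
series for the event rule, 1000 random vectors for the rank-correlation
oracle, and 40-eye cohorts for end-to-end determinism — sizes chosen to
make the Monte-Carlo checks decisive at conventional thresholds.

## Limitations

The sectorization is only as good as the cross-sectional damage contrast:
cohorts with little between-eye variance (or nearly uniform damage) leave
points unassigned or misassigned, and the anatomical correction then leans
on the trajectory prior. The normative defaults are placeholders. Real
24-2 geometry outside the central 16 points, MD/PSD computation, raw OCT
segmentation, and proprietary device formats are out of scope.
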