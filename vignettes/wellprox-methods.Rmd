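---
title: "Methods: proximity-based exposure and disparity analysis for oil and gas wells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-based exposure and disparity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wellprox)
```

## The analysis model

`wellprox` estimates, for each census block group and each 5-year study
period, the population exposed to oil and gas wells in each life-cycle
stage, and summarises demographic disparities in that exposure as group risk
ratios. The unit of analysis is the *block-group-period*: the same block
group observed under three ACS-style windows (2005–2009, 2010–2014,
2015–2019 by default; any non-overlapping calendar-year windows are
accepted).

### Well life-cycle stages

A well's history is reconstructed from its spud date (start of drilling),
completion date (end of preproduction), first/last production dates, annual
production volumes (BOE), and abandonment date. Per period:

* **new** — the preproduction interval `[spud, completion]` overlaps the
  period. Period membership of a date is by calendar year (`start_year <=
  year(d) <= end_year`), because 5-year ACS products are calendar-year
  aggregates.
* **active** — cumulative BOE within the period is strictly positive. The
  definitional identity `active <=> cumulative_boe > 0` is asserted across
  code paths in the tests. Dual membership is intentional: a well spudded in
  one year of a window and producing in a later year of the same window is
  both new and active there.
* **retired** — the well entered postproduction during the period: at the
  reported abandonment date, or, when none was reported, exactly 8 calendar
  years after the last production date (`idle_years` is configurable; 8
  matches the statutory long-term idle definition). The source of the
  retirement date ("abandonment" vs "idle") is retained, which lets users
  split retirements into plugged versus long-term idle wells.
* **plugged** — a cross-section, not a per-period stage: status marker
  plugged and abandonment date (when reported) not after the reference year
  (2019 by default). Plugged wells with no dates at all are assumed plugged
  before the reference year and included; wells whose abandonment postdates
  the reference year are excluded. Plugged exposure is attached to the final
  period only.

Decisions where the procedure was genuinely open:

* *Missing completion date*: the preproduction interval is open-ended on the
  right (the well is new in every period from spudding on, until evidence of
  completion). The alternative — dropping such wells from the new-well
  assessment — would undercount exposure in registries with patchy
  completion reporting.
* *Missing spud date with a completion date*: a single-point interval at the
  completion year. Completion marks the end of preproduction, so the well
  was certainly in preproduction some time that year; without a spud date
  the left end is unknown and the point interval is the conservative choice.
* *Retirement read per period*, not once over the whole study: each period's
  retired set is the wells whose postproduction start falls in that window,
  which is what per-period retirement counts require.
* *Dates*: ISO-8601 and year-only strings are accepted; year-only maps to
  July 1 (mid-year, minimising bias for mixed-granularity extracts). The
  8-year shift is calendar-exact; February 29 maps to March 1 in non-leap
  target years. Negative annual BOE entries (bookkeeping adjustments in real
  ledgers) are clamped to zero with a warning, since the activity rule is
  defined on produced volume.

### Exposure assessment

Two complementary protocols, both with a 1 km default radius (`radius_m`):

**Areal apportionment** answers *who is exposed*. All buffers of the wells
in a stage are dissolved into a single region, so overlapping per-well
buffers never double-count residents; the exposed fraction of a block group
is `area(geometry ∩ region) / area(geometry)`, and every demographic count
is multiplied by that fraction, unrounded. Real-valued exposed counts
preserve conservation exactly: the seven race/ethnicity groups partition the
population, and their exposed counts sum to the exposed total (asserted to
1e-9 in the tests). The simplifying assumption is uniform population density
within the block group.

**Centroid intensity** answers *how much*, among exposed block groups: the
number of wells of each stage within `radius_m` of the area-weighted
geometric centroid (boundary-inclusive — the tie set has measure zero, and
inclusivity is deterministic), and the within-period BOE summed over the
counted active wells. The centroid may fall outside a concave polygon; it is
used as-is (and flagged in verbose mode), matching the standard reading of
"block group centroid".

### Disparity statistics

The group risk ratio is
`RR = (Group_exposed / Group_total) / (Pop_exposed / Pop_total)`.
Race/ethnicity groups are compared against the total population;
socioeconomic indicators against their own universes (people below twice the
poverty line against the poverty universe, adults with fewer than 12 years
of education against the education universe, renter households against all
households, linguistically isolated adults against all adults, non-voters
against eligible voters — absent in the first period, where the group is
skipped). Undefined ratios (zero denominators) are emitted as `NA`, never as
zero and never dropped: silent drops would bias group comparisons. Ratios
are kept at full precision internally and rounded to 2 decimals only in
report tables.

Scopes: `state` (all block groups), `county:<name>` (both numerators and
denominators restricted to the county, i.e. comparison against county
composition), and production-intensity quintiles. Quintiles are
equal-frequency ranks of exposed block groups (positive centroid-radius BOE
only), computed per period; ties share the quintile of their smallest rank —
a deterministic rule under which an all-tied input lands entirely in
quintile 1. In the quintile tables the exposed numerators are
quintile-restricted while group and population totals stay statewide; this
reading guarantees the total-population self-group has RR 1 in every
occupied quintile, a property any sensible denominator convention must
satisfy, and empty quintiles surface as `NA` records.

The panel analysis compares the last two periods (same block-group
boundaries; mismatched geoid sets are fatal because block-group boundaries
are redefined each decennial census). Block groups are categorised by the
sign of the change in a metric — centroid new-well count, or centroid
cumulative BOE with "no change" meaning `|Δ| < 1e-6` BOE so floating-point
accumulation cannot create spurious categories — and demographic counts are
summed per category using the **later** period's counts (a configurable
convention; the procedure itself does not dictate the period, and the later
period matches the contemporaneous framing of the comparison).

## Geometry: numerical choices

No planar vector-geometry package is assumed; the package implements the
little geometry it needs directly, in a form chosen for verifiability:

* Discs are regular 64-gons (`n_seg`, minimum 8). A 64-gon's area is
  `(n/2) r² sin(2π/n)` ≈ 99.84% of the true disc, which is why the
  disc-area tests carry a 0.5% tolerance; the polygon form makes results
  bit-reproducible across runs.
* Areas of intersections with buffer unions use a vertical slab scanline:
  event abscissae are ring vertices, pairwise edge crossings between rings,
  and self-crossings of non-convex rings; between consecutive events the
  covered length along a vertical line is linear in x, so a midpoint
  evaluation integrates each slab exactly. No boolean polygon is ever
  constructed, which sidesteps the robustness pitfalls of polygon clipping.
  The independent check in the test suite is stratified Monte-Carlo point
  sampling with ray casting — a completely separate code path.
* Self-intersecting (bow-tie) input rings are kept, with a warning, under
  the even-odd interpretation, which is also how their area is measured.
  Zero-area geometries are fatal. Holes and multipolygons are supported
  throughout (even-odd parity).
* All geometry is planar in projected metres. Coordinates that look
  geographic (all within ±180/±90 with fractional parts) are refused: a 1 km
  buffer in degrees is meaningless. Reprojection is a documented pre-step.

## The synthetic-data generator

`generate_landscape()` emulates the statistical structure the analysis
assumes, with defaults fixed at magnitudes of the California study system:

* Block groups: an `nx × ny` tessellation of 2,500 m squares (rectangles
  keep areal intersections exactly computable for oracles). Populations are
  uniform on 600–3,000 (the typical block-group range), growing ~4.1% per
  period (~8.2% over two steps). Base race/ethnicity shares follow the
  statewide 2005–2009 composition (36.1% Hispanic/Latinx, 6.0% non-Hispanic
  Black, 42.5% non-Hispanic white, ...); socioeconomic rates are 11.6%
  poverty, 19.5% under-12-years education, 42.1% renters, 21.9%
  linguistically isolated, 28.4% non-voters, with voter fields absent in
  period 1.
* Wells: Poisson-sized clusters with Gaussian dispersion; spud year uniform
  1985–2018; preproduction 30–540 days; production lifetimes log-normal with
  mean ≈ 10.9 and SD ≈ 8.2 years; annual BOE log-normal
  (`meanlog 8, sdlog 2`, mean ≈ 22,000 BOE) to emulate the extreme right
  skew of real production; 73% of ended wells get a reported abandonment
  date (the rest retire via the idle rule); 44.3% of plugged wells have
  their last-production and abandonment dates blanked, mirroring the
  missing-date prevalence in real registries.
* Planted disparity: the target group's share is multiplied by
  `1 + (multiplier − 1)·exp(−d/L)` at distance `d` from the nearest well
  cluster (`L` = `length_scale`, default 1,500 m), then shares are
  renormalised. `multiplier = 1` gives a null landscape.
* Two demographic modes. *Sampled* draws multinomial race counts and
  binomial numerators — used for calibration tests. *Deterministic* uses
  expected counts, and with `planted_cells` places one always-active well at
  each listed cell centre; because the default cell (2,500 m) is at least
  twice the buffer radius, each disc lies strictly inside its own cell, the
  exposed fraction of a planted cell is exactly `disc_area / cell_area`, and
  `expected_rr()` computes the end-to-end risk ratios in closed form. The
  pipeline recovers them to 1e-6 (machine-level in practice), which is the
  package's parameter-recovery guarantee.
* All randomness flows through the configuration seed; identical seeds give
  byte-identical landscapes and output bundles.

What the generator does **not** emulate: real TIGER block-group shapes
(jitter aside, cells are rectangles), California's county structure or field
geography, spatial autocorrelation of socioeconomic indicators beyond the
single planted gradient, well re-activation after idling, and measurement
error in ACS estimates. Passing tests therefore demonstrate correctness of
the computational pipeline under known ground truth — not that any
particular real-world dataset is free of the data-quality issues the
validator is there to surface.

## Problem sizes and test design

The test suite favours small, fully checkable configurations: oracle
equivalence of the vectorised classifier on 200 randomised wells; geometric
oracles on 50 randomised landscapes of 4–9 wells each, each compared with a
stratified Monte-Carlo sample of 200,000 points at 3 binomial standard
errors; null calibration over 50 seeded replicates of a 16-cell landscape
(mean risk ratio of each race group within 3 standard errors of 1);
deterministic recovery on 36-cell planted landscapes. The replica of the
two-protocol illustration uses a 600 m square block group with one new well
at its centre, twelve active wells on a 500 m ring, and one retired well at
1,225 m east, whose 1 km buffer clips ≈ 10% of the block-group area.

## Limitations

Areal apportionment assumes uniform within-block-group population density;
dasymetric refinement (locating residences within block groups) is out of
scope, as are distance-decay weighting, multi-ring (3 km / 10 km) analyses,
emissions modelling, confidence intervals or hypothesis tests on risk
ratios, and any regression-based confounder adjustment. The pipeline reads
GeoJSON for geometries (no shapefile parser) and requires projected
coordinates. Legacy wells absent from registries are necessarily absent
here; the plugged cross-section inherits whatever under-reporting the input
carries.
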