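---
title: "Linking residence-area turnover to surface-water change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking residence-area turnover to surface-water change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromove)
```

## The question and the data model

Wetland specialist birds such as the Shoebill (*Balaeniceps rex*) live in
strongly seasonal swamp systems where the distribution of shallow surface
water — and with it, the distribution of catchable fish — changes within
weeks at the onset of the rainy season. `hydromove` implements an analysis
chain that asks two questions of hourly GPS telemetry and a surface-water
raster time series:

1. **Abandonment:** when a bird leaves a multi-day residence area, is that
   area getting drier or wetter?
2. **Selection:** does the newly chosen area have the same surface water
   as the one just abandoned?

The data model is deliberately small. GPS fixes are rows of
`(bird_id, timestamp, lon, lat)`, recorded hourly between 06:00 and 18:00
at a fixed UTC+02:00 offset — the birds' activity day — so "day" always
means local calendar day. Surface water is the Normalized Difference Water
Index, NDWI = (Green − NIR)/(Green + NIR), on a regular ~500 m grid
summarised over 8-day composite windows; +1 is open water, −1 dry ground,
and the index is used comparatively (drier vs wetter), never as an
absolute water depth.

## The pipeline, stage by stage

**Cleaning.** Fixes implying a speed above 150 km/h from the last retained
fix are removed by a sequential greedy filter. The greedy form (compare to
the last *retained* fix, walk left to right) was chosen because it is
deterministic, order-stable and idempotent; a visual-inspection step used
with field data is replaced by an optional user-supplied exclusion list.
Duplicate timestamps keep the first record. Age classes follow the
breeding calendar: a bird tagged as a juvenile is juvenile until the first
1 May after tagging, immature for the next two May-to-May years, and adult
afterwards; the windows partition the tracking span exactly.

**Daily displacement.** Each bird-day gets the maximum great-circle
distance (haversine, sphere radius 6371.0088 km) over all pairs of the
day's fixes. Movement between the last fix of one day and the first fix of
the next — night movement — is allocated to the earlier day:
`effective = max(daily max, outgoing night distance)`. Night allocation
applies only across consecutive calendar days; a tracking gap contributes
nothing. Days without fixes produce no record, because absence of data is
not absence of movement.

**Moving-Day threshold.** The threshold is the smallest whole-km value
such that at least 80% of bird-days fall strictly below it; days above it
are Moving Days. Whole-km rounding reflects how such thresholds are
reported and keeps the cut reproducible; the achieved coverage is reported
alongside. The threshold is fitted pooled across birds and age classes —
the displacement distributions of the classes are similar enough that a
single cut keeps the downstream segmentation comparable between them.

**Residence areas.** Inside each 1 October – 31 December analysis window
(the period of rapid water change), maximal runs of at least two
consecutive Staying days become candidate areas. A day exactly at the
threshold is a Staying day (moving means *more than* the threshold).
Consecutive candidate areas are compared by their 95% minimum convex
polygons — peel the `floor(0.05 n)` fixes farthest from the mean centroid,
hull the rest — and merged when the polygons intersect; merging pools
fixes and dates, recomputes the polygon, and continues left to right until
stable. Overlap includes a boundary touch, so the binary rule has no
unstable edge cases; degenerate polygons (fewer than three distinct
points, or collinear) are buffered by one raster cell (500 m) before the
test. Polygon work happens in a local equirectangular projection about the
window's mean coordinate; at residence-area scales (a few km) the
projection error is far below GPS error.

**Home ranges.** Utilisation distributions use a bivariate normal kernel
with the classical reference bandwidth
`h = 0.5 (sd_x + sd_y) n^{-1/6}` on a 500 m grid extending three
bandwidths beyond the data, normalised to unit mass. Isopleth areas take
cells in decreasing density order until the target mass is reached; at
tied densities, cells are included in index order until the mass is
reached, which keeps the reported *area* deterministic (the spatial mask
can differ among equal-density cells, the area cannot). Season-years run
May to April, the breeding calendar; seasons with fewer than 30 fixes are
skipped (configurable). Cumulative class-level ranges pool fixes rather
than averaging annual distributions — pooling answers "what ground does
the class use", which is the mapping question.

**NDWI sampling.** Each sample date is assigned to the single composite
whose half-open window `[start, start + 8 d)` contains it, provided the
composite passes QC (at least 92% good pixels and at most 2% unclassified,
both bounds inclusive). Values are read by nearest-cell lookup — the index
is a per-pixel classification, so interpolating across a land/water
boundary would not be meaningful — and averaged over the day's positions,
dropping missing cells; duplicate fixes in one cell are not deduplicated
(the mean is fix-weighted, like the field data it mirrors). Each residence
area emits four phases: *presence* (each occupied day at that day's own
fixes), *post-abandonment* (the 7 days after departure, re-evaluating the
occupancy-period fix locations on the later composites — the bird is gone,
so the occupied ground itself is re-measured), and the *last/first
occupied weeks* (truncated for shorter stays).

**Paired models.** Model (a) codes presence 0 and post-abandonment 1;
model (b) codes an area's last occupied week 0 against the *next* area's
first week 1, pairing only consecutive areas of the same bird and season —
an area without a successor contributes nothing. Both are binomial mixed
models (logit link, Laplace approximation, `lme4::glmer` with the bobyqa
optimiser) with random intercepts for year and for area nested within bird
(`bird:year:area` keys, so same-numbered areas of different birds never
pool). Model (a) uses an orthogonal second-degree polynomial of daily mean
NDWI, because abandonment can follow drying *and* wetting; the orthogonal
(not raw) basis gives comparable coefficient scales and makes the fit
invariant to affine rescaling of the index. Model (b) uses linear NDWI.
Fixed effects get Wald z tests; complete separation raises an error rather
than a silently divergent fit; a convergence flag, optimizer name and
tolerance are part of the fit report. Variance explained is the Nakagawa
decomposition with the logit distribution-specific variance π²/3:
marginal R² uses the fixed-effect predictor variance alone, conditional R²
adds the random-intercept variances.

## What the synthetic generator emulates

Field tracking data of this kind are typically available only on request,
so the package ships a generator whose defaults *are* the study
conditions, and every claim the tests make is made against it:

* hourly fixes 06:00–18:00 (+02:00), 13 per day;
* stays of geometric duration with mean 14 days, truncated at the 2-day
  minimum so every simulated stay can legally become an area;
* isotropic within-stay scatter of 300 m, which reproduces sub-km typical
  daily displacements;
* single relocation days with jumps of 8–30 km (morning fixes at the old
  centroid, afternoon at the new one), kept inside a ~35 km range disc per
  bird;
* 8-day, 500 m NDWI composites with baseline −0.5 (the birds sit on
  relatively dry ground), white cell noise (sd 0.06) re-drawn per window,
  and random intercepts for bird (sd 0.05), area (sd 0.06) and year
  (sd 0.02) so the mixed models face genuine grouping structure. The noise
  scales were chosen once so that daily mean NDWI spreads over roughly
  ±0.1 within a class, the order of spread the paired models plausibly
  face in the field;
* a per-area trend δ added to the area's raster footprint from the first
  composite containing post-abandonment days onward. Because a composite
  integrates 8 days, the straddling window already carries the change —
  drying begins as the bird leaves, so the contrast seen by model (a) is
  attenuated relative to δ, exactly as it would be with real composites.

Three presets pin the regimes of interest: `adults` (δ = −0.05, abandoned
areas dry), `immatures` (δ = +0.10, they wet) and `null` (δ = 0, the
regime in which model (b) should find nothing). The replicate studies in
the test suite use 5 birds × 3 seasons (adults) or 6 birds × 2 seasons,
about 1,700–2,000 paired rows per replicate, 50 seeded replicates per
preset — sizes chosen to give the recovery checks power while keeping a
full study under a few seconds on one core.

What the generator does *not* emulate: spatially autocorrelated NDWI
fields (noise is white across cells by default; a smoothed-noise flag
exists for realism experiments), behaviourally realistic movement
(no correlated random walks or state switching), rainfall or vegetation
covariates, and transmitter failure. Passing tests therefore demonstrate
that the chain recovers known structure of this form — not that any field
population behaves this way.

## Numerical choices and degenerate inputs

* Distances: haversine on a fixed-radius sphere; the ellipsoidal
  correction is below 0.5% at these scales and irrelevant to a whole-km
  threshold.
* A day exactly at the Moving-Day threshold stays; polygon boundary touch
  merges; both rules exist to make binary decisions deterministic.
* Single-fix days have zero daily maximum; single-area classes report
  `sd = 0` with an explicit flag; `href` refuses fewer than 5 points or
  zero spread and asks for a fixed bandwidth instead.
* NDWI at `green + nir = 0` is missing, never 0; samples with no covering
  QC-passing composite are skipped and counted, never imputed.
* The KDE grid normalises to unit mass exactly, so isopleth areas are
  comparisons of cell counts, not of floating-point tails; halving the
  cell size moves smooth-data isopleth areas by under 3%.
* Mixed-model convergence warnings are surfaced in the fit report (and in
  the manifest), not suppressed; with near-zero year variances the
  boundary ("singular") message from `lme4` is expected and benign.

## Known limitations

The within-window constancy of composites means daily samples inside one
window at similar places are highly correlated; with only ~7 rows per
area-phase this mildly inflates Wald statistics, which is visible in the
null-preset calibration sitting near (not comfortably above) its nominal
level. Aggregating to one row per area-window would trade this against
throwing away real day-to-day variation in bird position; the daily-row
design was kept because it is the field-standard formulation. The
equirectangular projection is adequate to ~300 km extents; continental
analyses would need a proper projected CRS. MCP overlap is a binary
merge criterion — no partial-overlap threshold is exposed — and the KDE
bandwidth is the reference rule only, which over-smooths strongly clumped
fixes; both match the analysis chain this package reproduces rather than
the state of the art in home-range estimation.

## A short worked example

```{r example, eval = FALSE}
fx <- end_to_end_fixture("adults", seed = 1)
run <- run_pipeline(fx$fixes, fx$rasters)
run$threshold
run$fits$a
stay_durations(run$segmentation[["2015"]])
```

The acceptance script `scripts/acceptance.R` re-runs exactly this chain on
the three presets and writes the headline quantities (threshold, area
counts, phase NDWI means and shifts, sign-recovery rates, null model p and
marginal R², mean annual range) as JSON.
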