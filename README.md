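# hydromove

Movement ecology of wetland birds against changing surface water.
`hydromove` is an R package plus a numbered analysis workflow that links
hourly GPS telemetry to a surface-water raster time series: it cleans
tracks, measures daily displacement, finds the Moving-Day threshold,
segments trajectories into multi-day residence **Areas**, estimates kernel
home ranges, samples **NDWI** (Normalized Difference Water Index,
(Green − NIR)/(Green + NIR)) at bird positions from 8-day composites, and
fits two paired binomial mixed models:

* **model (a)** — presence (0) vs the week after abandonment (1), NDWI as
  an orthogonal degree-2 polynomial: do abandoned areas dry or wet?
* **model (b)** — last week before abandonment (0) vs first week after
  arrival in the next area (1), linear NDWI: do birds pick areas with the
  surface water they just left?

Both use random intercepts for year and for area nested within bird, Wald
z tests, and Nakagawa marginal/conditional R² (logit-link variance π²/3).
Because tracking data of this kind are usually available only on request,
the package ships a seeded synthetic generator (trajectories + NDWI
rasters with known ground truth) against which every stage is tested.

Written for movement ecologists and remote-sensing-adjacent analysts who
want the full chain — from raw fixes to Table-style model reports — as
small, testable functions rather than a monolithic script.

## Worked example

```r
library(hydromove)

fx  <- end_to_end_fixture("adults", seed = 1)   # 5 birds x 3 seasons, drying delta = -0.05
run <- run_pipeline(fx$fixes, fx$rasters)

run$threshold
#> <moving-day threshold: 2 km (94.1% of 1380 days below; target 80%)>

run
#> <pipeline run: 17940 fixes -> 1380 bird-days, threshold 2 km, 91 areas, 2906 samples, 2 model(s)>

mean(run$areas$duration_days)
#> [1] 14.27473
```

The threshold (2 km here) is the smallest whole-km cut with at least 80%
of bird-days below it; days above it are relocations. The 91 residence
areas last on average ~14 days. The fitted abandonment model then shows
drier post-abandonment samples — presence mean NDWI −0.514 against
−0.553 the week after departure, recovering the simulated −0.05 drying
trend (attenuated by the 8-day composite straddling the departure).

The same chain as a readable sequence of drivers:

```sh
Rscript analysis/01_simulate.R       # presets -> results/sim (CSV, .asc rasters, truth JSON)
Rscript analysis/02_movement.R       # daily metrics, monthly means, threshold
Rscript analysis/03_segmentation.R   # areas per season, GeoJSON polygons
Rscript analysis/04_home_range.R     # annual kernel ranges, pooled range
Rscript analysis/05_surface_water.R  # phase-labelled NDWI samples
Rscript analysis/06_models.R         # paired GLMMs, response curves
```

Each driver states what it found and writes its tables under `results/`.

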