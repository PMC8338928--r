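#!/usr/bin/env Rscript
# Kernel home ranges per bird and season-year (95% and 50% isopleths,
# href bandwidth, 500 m grid) on the adults preset, plus the pooled
# cumulative range across birds.

suppressMessages(library(hydromove))

dir.create("results/home_range", recursive = TRUE, showWarnings = FALSE)

fixes <- filter_speed_outliers(read_fixes("results/sim/adults_fixes.csv"))$fixes
ranges <- annual_ranges(fixes)
readr::write_csv(ranges, "results/home_range/annual_ranges.csv")
readr::write_csv(range_summary(ranges), "results/home_range/range_summary.csv")

pooled <- pooled_range(fixes)
write_ascii_grid(pooled$grid, "results/home_range/cumulative_ud.asc")

message(sprintf(
  "%d bird-seasons; mean 95%% range %.0f km2 (sd %.0f), mean 50%% core %.0f km2; pooled 95%% %.0f km2",
  nrow(ranges), mean(ranges$area_km2_95), stats::sd(ranges$area_km2_95),
  mean(ranges$area_km2_50), pooled$area_km2_95
))
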