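#!/usr/bin/env Rscript
# Sample daily mean NDWI at bird positions for every residence area:
# presence days at the day's own fixes, the 7 days after abandonment at
# the occupancy-period locations, and the first/last occupied weeks.

suppressMessages(library(hydromove))

dir.create("results/surface_water", recursive = TRUE, showWarnings = FALSE)

for (preset in c("adults", "immatures", "null")) {
  fixes <- filter_speed_outliers(
    read_fixes(sprintf("results/sim/%s_fixes.csv", preset))
  )$fixes
  daily <- readr::read_csv(sprintf("results/movement/%s_daily.csv", preset),
    show_col_types = FALSE
  )
  thr <- jsonlite::read_json(sprintf("results/movement/%s_threshold.json", preset))
  stack <- read_composite_dir(sprintf("results/sim/%s_rasters", preset))
  proj <- attr(stack, "proj")

  samples <- list()
  for (yr in sort(unique(as.integer(format(daily$date, "%Y"))))) {
    seg <- segment_areas(daily, fixes, thr$threshold_km,
      window = as.Date(sprintf("%d-%s", yr, c("10-01", "12-31"))), proj = proj
    )
    if (nrow(seg$areas) == 0) next
    samples[[as.character(yr)]] <- phase_samples_all(seg, stack, year = yr)
  }
  samples <- dplyr::bind_rows(samples)
  readr::write_csv(samples, sprintf("results/surface_water/%s_samples.csv", preset))

  by_phase <- dplyr::summarise(
    dplyr::group_by(samples, .data$phase),
    mean_ndwi = mean(.data$daily_mean_ndwi), n = dplyr::n()
  )
  message(preset, ":")
  for (i in seq_len(nrow(by_phase))) {
    message(sprintf(
      "  %-22s %6.3f (n = %d)", by_phase$phase[i], by_phase$mean_ndwi[i], by_phase$n[i]
    ))
  }
}
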