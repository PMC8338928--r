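#!/usr/bin/env Rscript
# Generate the three synthetic study presets (drying "adults", wetting
# "immatures", and a no-change null) and write their tracks, rasters and
# ground truth under results/sim/. Downstream scripts read these files, so
# the whole analysis also exercises the pipeline's file formats.

suppressMessages(library(hydromove))

seed <- as.integer(Sys.getenv("HM_SEED", "1"))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (preset in c("adults", "immatures", "null")) {
  fx <- end_to_end_fixture(preset, seed = seed)
  write_fixes(fx$fixes, file.path(out, paste0(preset, "_fixes.csv")))
  write_truth_json(fx$truth, file.path(out, paste0(preset, "_truth.json")))
  rdir <- file.path(out, paste0(preset, "_rasters"))
  dir.create(rdir, showWarnings = FALSE)
  meta <- lapply(seq_along(fx$rasters), function(i) {
    comp <- fx$rasters[[i]]
    f <- sprintf("ndwi_%s.asc", format(comp$window_start))
    write_ascii_grid(comp$grid, file.path(rdir, f))
    list(
      file = f, window_start = format(comp$window_start),
      qc_good = comp$qc_good, qc_unclassified = comp$qc_unclassified
    )
  })
  jsonlite::write_json(
    list(
      proj = list(lon0 = fx$truth$proj$lon0, lat0 = fx$truth$proj$lat0),
      composites = meta
    ),
    file.path(rdir, "index.json"),
    auto_unbox = TRUE, digits = NA
  )
  message(sprintf(
    "%-10s %6d fixes, %3d true areas, %2d composites -> %s",
    preset, nrow(fx$fixes), nrow(fx$truth$areas), length(fx$rasters), out
  ))
}
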