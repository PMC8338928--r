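# End-to-end orchestration: clean -> daily metrics -> threshold ->
# per-season segmentation -> NDWI sampling -> paired models, with a
# reproducible run manifest.

#' Pipeline configuration
#'
#' @param window_start_md,window_end_md Month-day bounds of the seasonal
#'   analysis window (default October 1 - December 31, the period of
#'   rapid surface-water change at the start of the rainy season).
#' @param max_kmh Speed-outlier threshold (km/h).
#' @param threshold_level,threshold_step_km Moving-Day threshold settings.
#' @param retain MCP retention fraction.
#' @param buffer_m Degenerate-MCP buffer (one raster cell).
#' @param models Which paired models to fit: `"a"`, `"b"` or both.
#' @param min_rows Minimum design rows required to attempt a fit.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_start_md = "10-01",
                            window_end_md = "12-31",
                            max_kmh = 150,
                            threshold_level = 0.80,
                            threshold_step_km = 1,
                            retain = 0.95,
                            buffer_m = 500,
                            models = c("a", "b"),
                            min_rows = 20) {
  structure(
    list(
      window_start_md = window_start_md, window_end_md = window_end_md,
      max_kmh = max_kmh, threshold_level = threshold_level,
      threshold_step_km = threshold_step_km, retain = retain,
      buffer_m = buffer_m, models = models, min_rows = min_rows
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: speed-outlier cleaning, daily displacement metrics,
#' Moving-Day threshold (pooled over all bird-days), per-season-year
#' segmentation inside the analysis window, phase-labelled NDWI sampling,
#' design construction and both binomial mixed models (poly-2 NDWI for the
#' abandonment model, linear NDWI for the area-selection model). Any stage
#' failure aborts with the stage name. The returned manifest records
#' per-stage record counts, the threshold, a hash of the configuration and
#' of each stage's output, so reruns can be checked for bit-identical
#' behaviour.
#'
#' @param fixes Raw fixes tibble ([read_fixes()] or
#'   [simulate_tracks()]`$fixes`).
#' @param rasters List of `ndwi_composite`s with a `proj` attribute (or
#'   `NULL` to stop after segmentation).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: `cleaned`, `daily`,
#'   `threshold`, `segmentation` (list per season-year), `samples`,
#'   `designs`, `fits`, `manifest`.
#' @export
run_pipeline <- function(fixes, rasters = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cleaned <- stage("clean", filter_speed_outliers(fixes, max_kmh = config$max_kmh))
  daily <- stage("metrics", daily_movements(cleaned$fixes))
  threshold <- stage("threshold", fit_moving_threshold(
    daily,
    level = config$threshold_level, rounding_km = config$threshold_step_km
  ))

  proj <- if (!is.null(rasters)) attr(rasters, "proj") else NULL
  seasons <- sort(unique(as.integer(format(daily$date, "%Y"))))
  segs <- list()
  all_samples <- list()
  for (yr in seasons) {
    win <- as.Date(sprintf("%d-%s", yr, c(config$window_start_md, config$window_end_md)))
    in_win <- daily$date >= win[1] & daily$date <= win[2]
    if (!any(in_win)) next
    seg <- stage("segment", segment_areas(
      daily, cleaned$fixes, threshold,
      window = win, proj = proj,
      retain = config$retain, buffer_m = config$buffer_m
    ))
    segs[[as.character(yr)]] <- seg
    if (!is.null(rasters) && nrow(seg$areas) > 0) {
      all_samples[[as.character(yr)]] <- stage(
        "sample",
        phase_samples_all(seg, rasters, year = yr)
      )
    }
  }
  samples <- dplyr::bind_rows(all_samples)
  if (!is.null(rasters) && length(segs) > 0 && nrow(samples) == 0) {
    stage("sample", stop("no samples could be drawn: rasters do not cover the analysis window"))
  }

  designs <- list()
  fits <- list()
  if (!is.null(rasters) && nrow(samples) > 0) {
    for (m in config$models) {
      designs[[m]] <- stage("design", build_design(samples, model = m))
      if (nrow(designs[[m]]) >= config$min_rows &&
        length(unique(designs[[m]]$response)) == 2) {
        fits[[m]] <- stage("fit", fit_binomial_glmm(
          designs[[m]],
          fixed = if (m == "a") "poly2" else "linear"
        ))
      }
    }
  }

  areas_tbl <- dplyr::bind_rows(lapply(names(segs), function(yr) {
    a <- segs[[yr]]$areas
    if (nrow(a) == 0) {
      return(NULL)
    }
    tibble::tibble(
      bird_id = a$bird_id, year = as.integer(yr), area_id = a$area_id,
      start_date = a$start_date, end_date = a$end_date,
      duration_days = a$duration_days, n_fixes = a$n_fixes,
      abandoned = a$abandoned
    )
  }))

  manifest <- list(
    versions = list(
      hydromove = as.character(utils::packageVersion("hydromove")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    ),
    config = unclass(config),
    counts = list(
      fixes_in = nrow(fixes),
      fixes_removed = nrow(cleaned$removed),
      bird_days = nrow(daily),
      moving_days = sum(vapply(segs, function(s) nrow(s$moving_days), 0L)),
      areas = nrow(areas_tbl),
      samples = nrow(samples),
      design_rows = lapply(designs, nrow)
    ),
    threshold_km = threshold$threshold_km,
    threshold_coverage = threshold$coverage,
    hashes = list(
      config = rlang::hash(unclass(config)),
      daily = rlang::hash(daily),
      areas = rlang::hash(areas_tbl),
      samples = rlang::hash(samples),
      fits = rlang::hash(lapply(fits, function(f) list(f$terms, f$ranef_var, f$r2)))
    )
  )
  structure(
    list(
      cleaned = cleaned, daily = daily, threshold = threshold,
      segmentation = segs, areas = areas_tbl, samples = samples,
      designs = designs, fits = fits, manifest = manifest
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline run: %d fixes -> %d bird-days, threshold %g km, %d areas, %d samples, %d model(s)>\n",
    x$manifest$counts$fixes_in, x$manifest$counts$bird_days,
    x$manifest$threshold_km, x$manifest$counts$areas,
    x$manifest$counts$samples, length(x$fits)
  ))
  invisible(x)
}

#' Write a run manifest as JSON
#' @param run A `pipeline_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
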