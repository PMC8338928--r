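# Partition a trajectory into residence "Areas": runs of at least two
# consecutive Staying days between Moving Days, with consecutive runs
# merged when their 95% MCPs overlap (the bird never really left).

#' Segment trajectories into residence areas
#'
#' Within the analysis window, each bird-day is labelled Moving when its
#' effective displacement strictly exceeds the threshold, otherwise
#' Staying (a day exactly at the threshold stays). Maximal runs of two or
#' more consecutive Staying calendar days become candidate Areas; shorter
#' runs are discarded (and logged). For each pair of consecutive candidate
#' Areas of a bird the 95% MCPs are compared: if they overlap (including a
#' boundary touch) the two are merged — fixes and dates pooled, the MCP
#' recomputed — and the merged polygon is compared with the next Area;
#' passes repeat until no merge occurs.
#'
#' @param daily Output of [daily_movements()].
#' @param fixes The fixes tibble the metrics came from.
#' @param threshold A `moving_threshold` object (or a number, km).
#' @param window Length-2 Date vector (inclusive); `NULL` uses the full
#'   data span.
#' @param proj A [local_projection()]; default is built about the mean
#'   coordinate of the windowed fixes.
#' @param retain MCP retention fraction (default 0.95).
#' @param buffer_m Buffer for degenerate MCPs in the overlap test,
#'   conventionally one raster grid cell (default 500 m).
#' @return An object of class `segmentation`: list with
#'   \describe{
#'     \item{areas}{tibble: `bird_id`, `area_id`, `start_date`, `end_date`,
#'       `duration_days`, `n_fixes`, `abandoned`, plus list-columns `days`
#'       (occupied dates), `fix_rows` (tibbles of member fixes with planar
#'       `x`,`y`) and `mcp`.}
#'     \item{moving_days}{tibble: `bird_id`, `date`.}
#'     \item{merge_log}{tibble of overlap decisions.}
#'     \item{discarded_runs}{tibble of staying runs shorter than 2 days.}
#'     \item{proj, threshold_km, window}{as used.}
#'   }
#' @export
segment_areas <- function(daily, fixes, threshold, window = NULL,
                          proj = NULL, retain = 0.95, buffer_m = 500) {
  thr_km <- if (inherits(threshold, "moving_threshold")) threshold$threshold_km else threshold
  stopifnot(is.numeric(thr_km), thr_km > 0)
  fx <- fixes
  fx$date <- as.Date(fx$timestamp, tz = HM_TZ)
  if (!is.null(window)) {
    window <- as.Date(window)
    stopifnot(length(window) == 2, window[1] <= window[2])
    daily <- daily[daily$date >= window[1] & daily$date <= window[2], , drop = FALSE]
    fx <- fx[fx$date >= window[1] & fx$date <= window[2], , drop = FALSE]
  } else {
    window <- range(daily$date)
  }
  if (nrow(daily) == 0) {
    return(empty_segmentation(proj, thr_km, window))
  }
  if (is.null(proj)) proj <- local_projection(mean(fx$lon), mean(fx$lat))
  xy <- project_xy(proj, fx$lon, fx$lat)
  fx$x <- xy$x
  fx$y <- xy$y

  areas_list <- list()
  moving_list <- list()
  merge_log <- list()
  discarded <- list()

  for (b in unique(daily$bird_id)) {
    dd <- daily[daily$bird_id == b, , drop = FALSE]
    dd <- dd[order(dd$date), , drop = FALSE]
    moving <- dd$effective_distance_km > thr_km
    moving_list[[b]] <- tibble::tibble(bird_id = b, date = dd$date[moving])
    stay_dates <- dd$date[!moving]
    if (length(stay_dates) == 0) next
    runs <- split_consecutive(stay_dates)
    short <- lengths(runs) < 2
    if (any(short)) {
      discarded[[b]] <- tibble::tibble(
        bird_id = b,
        start_date = as.Date(vapply(runs[short], function(r) as.character(min(r)), "")),
        n_days = lengths(runs[short])
      )
    }
    runs <- runs[!short]
    if (length(runs) == 0) next
    cand <- lapply(runs, function(r) make_area(b, r, fx, retain))
    cand <- Filter(Negate(is.null), cand)
    # left-to-right merge cascade, repeated until stable
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < length(cand)) {
        ov <- mcp_overlap(cand[[i]]$mcp, cand[[i + 1]]$mcp, buffer_m = buffer_m)
        merge_log[[length(merge_log) + 1]] <- tibble::tibble(
          bird_id = b,
          left_start = cand[[i]]$start_date, right_start = cand[[i + 1]]$start_date,
          overlap = ov
        )
        if (ov) {
          cand[[i]] <- make_area(
            b, sort(unique(c(cand[[i]]$days, cand[[i + 1]]$days))), fx, retain
          )
          cand[[i + 1]] <- NULL
          merged_any <- TRUE
        } else {
          i <- i + 1
        }
      }
      if (!merged_any) break
    }
    last_day <- max(dd$date)
    for (k in seq_along(cand)) {
      a <- cand[[k]]
      a$area_id <- k
      a$abandoned <- a$end_date < last_day
      areas_list[[length(areas_list) + 1]] <- a
    }
  }

  areas <- if (length(areas_list) == 0) {
    empty_area_tbl()
  } else {
    tibble::tibble(
      bird_id = vapply(areas_list, `[[`, "", "bird_id"),
      area_id = vapply(areas_list, `[[`, 0L, "area_id"),
      start_date = as.Date(vapply(areas_list, function(a) as.character(a$start_date), "")),
      end_date = as.Date(vapply(areas_list, function(a) as.character(a$end_date), "")),
      duration_days = vapply(areas_list, `[[`, 0L, "duration_days"),
      n_fixes = vapply(areas_list, `[[`, 0L, "n_fixes"),
      abandoned = vapply(areas_list, `[[`, TRUE, "abandoned"),
      days = lapply(areas_list, `[[`, "days"),
      fix_rows = lapply(areas_list, `[[`, "fix_rows"),
      mcp = lapply(areas_list, `[[`, "mcp")
    )
  }
  structure(
    list(
      areas = areas,
      moving_days = dplyr::bind_rows(moving_list),
      merge_log = dplyr::bind_rows(merge_log),
      discarded_runs = dplyr::bind_rows(discarded),
      proj = proj,
      threshold_km = thr_km,
      window = window
    ),
    class = "segmentation"
  )
}

make_area <- function(bird, run_dates, fx, retain) {
  rows <- fx[fx$bird_id == bird & fx$date %in% run_dates, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(NULL)
  }
  list(
    bird_id = bird,
    days = run_dates,
    start_date = min(run_dates),
    end_date = max(run_dates),
    duration_days = as.integer(max(run_dates) - min(run_dates)) + 1L,
    n_fixes = nrow(rows),
    fix_rows = rows,
    mcp = mcp_polygon(rows$x, rows$y, retain = retain)
  )
}

split_consecutive <- function(dates) {
  dates <- sort(unique(dates))
  grp <- cumsum(c(1, as.integer(diff(dates)) != 1))
  unname(split(dates, grp))
}

empty_area_tbl <- function() {
  tibble::tibble(
    bird_id = character(), area_id = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    duration_days = integer(), n_fixes = integer(), abandoned = logical(),
    days = list(), fix_rows = list(), mcp = list()
  )
}

empty_segmentation <- function(proj, thr_km, window) {
  structure(
    list(
      areas = empty_area_tbl(),
      moving_days = tibble::tibble(bird_id = character(), date = as.Date(character())),
      merge_log = tibble::tibble(),
      discarded_runs = tibble::tibble(),
      proj = proj, threshold_km = thr_km, window = window
    ),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation: %d areas, %d moving days, threshold %g km, %s..%s>\n",
    nrow(x$areas), nrow(x$moving_days), x$threshold_km,
    format(x$window[1]), format(x$window[2])
  ))
  invisible(x)
}

#' Mean and SD of residence durations per age class
#'
#' Sample (n-1) standard deviation; a class with a single area reports
#' `sd = 0` with `sd_defined = FALSE`.
#'
#' @param seg A `segmentation` object (or an `areas` tibble).
#' @param age_windows Optional age windows; class is taken at each area's
#'   start date. `NULL` pools into class `"all"`.
#' @return A tibble: `age_class`, `n_areas`, `mean_days`, `sd_days`,
#'   `sd_defined`.
#' @export
stay_durations <- function(seg, age_windows = NULL) {
  areas <- if (inherits(seg, "segmentation")) seg$areas else seg
  stopifnot(nrow(areas) >= 1)
  cls <- if (is.null(age_windows)) {
    rep("all", nrow(areas))
  } else {
    age_class_at(areas$start_date, age_windows, areas$bird_id)
  }
  tibble::tibble(age_class = cls, duration = areas$duration_days) |>
    dplyr::filter(!is.na(.data$age_class)) |>
    dplyr::group_by(.data$age_class) |>
    dplyr::summarise(
      n_areas = dplyr::n(),
      mean_days = mean(.data$duration),
      sd_days = dplyr::if_else(dplyr::n() > 1, stats::sd(.data$duration), 0),
      sd_defined = dplyr::n() > 1,
      .groups = "drop"
    )
}

#' Export residence areas as GeoJSON
#'
#' MCP polygons are unprojected back to lon/lat; properties carry bird,
#' dates and duration.
#'
#' @param seg A `segmentation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
areas_to_geojson <- function(seg, path) {
  feats <- lapply(seq_len(nrow(seg$areas)), function(i) {
    a <- seg$areas[i, ]
    m <- a$mcp[[1]]
    v <- m$vertices
    ll <- unproject_xy(seg$proj, v[, 1], v[, 2])
    ring <- cbind(ll$lon, ll$lat)
    ring <- rbind(ring, ring[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(
        bird_id = a$bird_id, area_id = a$area_id,
        start_date = format(a$start_date), end_date = format(a$end_date),
        duration_days = a$duration_days, degenerate = m$degenerate
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(apply(ring, 1, identity, simplify = FALSE))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
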