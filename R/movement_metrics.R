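# Daily displacement metrics, monthly summaries, and the Moving-Day
# threshold that splits routine foraging movement from relocations.

#' Per-day maximum displacement with night allocation
#'
#' For each bird-day with at least one fix: the maximum great-circle
#' distance among all pairs of that day's fixes (`max_daily_distance_km`;
#' 0 for single-fix days), the distance from the previous day's last fix to
#' this day's first fix (`night_distance_km`, the night *into* this day,
#' only when the previous record is the immediately preceding calendar
#' day), and the effective displacement
#' `effective_distance_km = max(max_daily_distance_km, outgoing night
#' distance)` — night movements are allocated to the day they started, so
#' a bird that relocates after its last evening fix is credited with the
#' move on that day. Days with no fixes produce no record.
#'
#' @param fixes A fixes tibble (see [read_fixes()]), speed-filtered.
#' @return A tibble: `bird_id`, `date`, `n_fixes`, `max_daily_distance_km`,
#'   `night_distance_km`, `effective_distance_km`.
#' @export
daily_movements <- function(fixes) {
  if (nrow(fixes) == 0) {
    return(tibble::tibble(
      bird_id = character(), date = as.Date(character()), n_fixes = integer(),
      max_daily_distance_km = numeric(), night_distance_km = numeric(),
      effective_distance_km = numeric()
    ))
  }
  df <- fixes
  df$date <- as.Date(df$timestamp, tz = HM_TZ)
  per_day <- df |>
    dplyr::arrange(.data$bird_id, .data$timestamp) |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(
      n_fixes = dplyr::n(),
      max_daily_distance_km = max_pairwise_km(.data$lon, .data$lat),
      first_lon = dplyr::first(.data$lon), first_lat = dplyr::first(.data$lat),
      last_lon = dplyr::last(.data$lon), last_lat = dplyr::last(.data$lat),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bird_id, .data$date)

  per_day <- per_day |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::mutate(
      night_distance_km = dplyr::if_else(
        !is.na(dplyr::lag(.data$date)) & .data$date == dplyr::lag(.data$date) + 1,
        great_circle_km(
          dplyr::lag(.data$last_lon), dplyr::lag(.data$last_lat),
          .data$first_lon, .data$first_lat
        ),
        0
      ),
      effective_distance_km = pmax(
        .data$max_daily_distance_km,
        dplyr::coalesce(dplyr::lead(.data$night_distance_km), 0)
      )
    ) |>
    dplyr::ungroup()

  per_day[, c(
    "bird_id", "date", "n_fixes", "max_daily_distance_km",
    "night_distance_km", "effective_distance_km"
  )]
}

#' Mean maximum daily distance per bird, age class and month
#'
#' Monthly means of the effective daily displacement, grouped by bird, age
#' class, and calendar month within year. The `month_label` factor is
#' ordered May through April so summaries and figures start at the
#' beginning of the breeding season.
#'
#' @param daily Output of [daily_movements()].
#' @param age_windows Age windows from [assign_age_windows()]; `NULL`
#'   pools everything into class `"all"`.
#' @return A tibble: `bird_id`, `age_class`, `year`, `month`,
#'   `month_label`, `mean_max_daily_km`, `n_days`.
#' @export
monthly_mean_max_distance <- function(daily, age_windows = NULL) {
  stopifnot(nrow(daily) > 0)
  cls <- if (is.null(age_windows)) {
    rep("all", nrow(daily))
  } else {
    age_class_at(daily$date, age_windows, daily$bird_id)
  }
  month_levels <- month.abb[c(5:12, 1:4)]
  daily |>
    dplyr::mutate(
      age_class = cls,
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::filter(!is.na(.data$age_class)) |>
    dplyr::group_by(.data$bird_id, .data$age_class, .data$year, .data$month) |>
    dplyr::summarise(
      mean_max_daily_km = mean(.data$effective_distance_km),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      month_label = factor(month.abb[.data$month], levels = month_levels, ordered = TRUE)
    ) |>
    dplyr::arrange(.data$bird_id, .data$age_class, .data$year, .data$month_label)
}

#' Moving-Day threshold from the displacement distribution
#'
#' The threshold is the smallest multiple of `rounding_km` such that at
#' least a fraction `level` of bird-days have effective displacement
#' strictly below it. Days at or above the threshold are "Moving Days".
#' Rounding to a whole-km step reflects how such thresholds are reported
#' (e.g. a round 3 km capturing ~80% of days) and makes the cut
#' reproducible.
#'
#' @param daily Output of [daily_movements()] (needs >= 10 days).
#' @param level Target coverage fraction (default 0.80).
#' @param rounding_km Candidate step in km (default 1).
#' @return An object of class `moving_threshold`: list with `level`,
#'   `threshold_km`, `coverage` (achieved fraction of days strictly below
#'   the threshold), `n_days`.
#' @export
fit_moving_threshold <- function(daily, level = 0.80, rounding_km = 1) {
  stopifnot(level > 0, level < 1, rounding_km > 0)
  d <- daily$effective_distance_km
  if (length(d) < 10) stop("need at least 10 bird-days to fit a threshold")
  k <- 1
  repeat {
    thr <- k * rounding_km
    if (mean(d < thr) >= level) break
    k <- k + 1
  }
  structure(
    list(
      level = level,
      threshold_km = thr,
      coverage = mean(d < thr),
      n_days = length(d)
    ),
    class = "moving_threshold"
  )
}

#' @export
print.moving_threshold <- function(x, ...) {
  cat(sprintf(
    "<moving-day threshold: %g km (%.1f%% of %d days below; target %.0f%%)>\n",
    x$threshold_km, 100 * x$coverage, x$n_days, 100 * x$level
  ))
  invisible(x)
}

#' Write a threshold report as JSON
#' @param threshold A `moving_threshold` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(threshold, path) {
  jsonlite::write_json(unclass(threshold), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
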