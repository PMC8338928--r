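# Small fixture builders shared across test files.

TEST_PROJ <- local_projection(30.2, -12.0)

# Fixes for one bird from per-day planar centroids (metres): `n_per_day`
# fixes scattered around each day's centroid, hourly from 06:00.
traj_from_centroids <- function(bird, start_date, cx, cy, scatter_m = 100,
                                n_per_day = 13, seed = 1, proj = TEST_PROJ) {
  stopifnot(length(cx) == length(cy))
  withr::with_seed(seed, {
    rows <- lapply(seq_along(cx), function(i) {
      x <- cx[i] + stats::rnorm(n_per_day, 0, scatter_m)
      y <- cy[i] + stats::rnorm(n_per_day, 0, scatter_m)
      ll <- unproject_xy(proj, x, y)
      tibble::tibble(
        bird_id = bird,
        timestamp = as.POSIXct(
          sprintf(
            "%s %02d:00:00", format(as.Date(start_date) + i - 1),
            6 + seq_len(n_per_day) - 1
          ),
          tz = HM_TZ
        ),
        lon = ll$lon, lat = ll$lat
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Fixes placed exactly at given lon/lat points on one day, hourly.
fixes_at <- function(bird, date, lon, lat, start_hour = 6) {
  tibble::tibble(
    bird_id = bird,
    timestamp = as.POSIXct(
      sprintf("%s %02d:00:00", format(as.Date(date)), start_hour + seq_along(lon) - 1),
      tz = HM_TZ
    ),
    lon = lon, lat = lat
  )
}

# A constant-valued composite stack covering [start, start + n_windows * 8).
flat_stack <- function(start, values, grid_args = list(x0 = -5000, y0 = -5000, cell = 500, nx = 20, ny = 20),
                       qc_good = 0.98, qc_unclassified = 0.005) {
  start <- as.Date(start)
  stack <- lapply(seq_along(values), function(i) {
    g <- do.call(planar_grid, c(grid_args, list(values = values[i])))
    ndwi_composite(start + (i - 1) * 8, g,
      qc_good = qc_good[min(i, length(qc_good))],
      qc_unclassified = qc_unclassified[min(i, length(qc_unclassified))]
    )
  })
  attr(stack, "proj") <- TEST_PROJ
  stack
}

# A one-row area tibble in the shape segment_areas() produces.
manual_area <- function(bird = "A", area_id = 1L, start, n_days,
                        x = 0, y = 0, abandoned = TRUE) {
  start <- as.Date(start)
  days <- start + seq_len(n_days) - 1
  fx <- tibble::tibble(
    date = rep(days, each = 3),
    x = rep(x, 3 * n_days) + rep(c(-100, 0, 100), n_days),
    y = rep(y, 3 * n_days)
  )
  tibble::tibble(
    bird_id = bird, area_id = area_id,
    start_date = start, end_date = days[n_days],
    duration_days = n_days, n_fixes = nrow(fx), abandoned = abandoned,
    days = list(days), fix_rows = list(fx),
    mcp = list(mcp_polygon(fx$x, fx$y))
  )
}

# Phase-sample rows for hand-built designs.
manual_samples <- function(bird, area_id, year, phase, values, start = "2015-10-01") {
  tibble::tibble(
    bird_id = bird, date = as.Date(start) + seq_along(values) - 1,
    area_id = area_id, year = year, phase = phase, daily_mean_ndwi = values
  )
}
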