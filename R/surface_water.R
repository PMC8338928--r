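# NDWI composites and daily-mean sampling at bird positions.
#
# NDWI (McFeeters): (Green - NIR) / (Green + NIR); +1 open water, -1 dry
# land. Composites summarise 8 days of imagery in one ~500 m raster; the
# window is half-open [start, start + 8 days) so every date belongs to
# exactly one composite.

#' NDWI from green and near-infrared reflectance
#'
#' @param green,nir Non-negative reflectances (vectors, matrices or
#'   `planar_grid`s of matching shape).
#' @return Values in `[-1, 1]`; cells with `green + nir == 0` are
#'   undefined and returned as `NA` (never 0).
#' @export
ndwi <- function(green, nir) {
  if (inherits(green, "planar_grid")) {
    stopifnot(inherits(nir, "planar_grid"), green$nx == nir$nx, green$ny == nir$ny)
    out <- green
    out$values <- ndwi(green$values, nir$values)
    return(out)
  }
  stopifnot(all(green >= 0, na.rm = TRUE), all(nir >= 0, na.rm = TRUE))
  denom <- green + nir
  out <- (green - nir) / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Construct an 8-day NDWI composite
#'
#' @param window_start First date of the composite window (the window is
#'   `[window_start, window_start + window_days)`).
#' @param grid A `planar_grid` of NDWI values in `[-1, 1]` (NA = missing).
#' @param qc_good Fraction of good-quality pixels reported by the
#'   provider's QC layer.
#' @param qc_unclassified Fraction of unclassified pixels.
#' @param window_days Window length (default 8).
#' @return An object of class `ndwi_composite`.
#' @export
ndwi_composite <- function(window_start, grid, qc_good = 1, qc_unclassified = 0,
                           window_days = 8) {
  stopifnot(inherits(grid, "planar_grid"))
  rng <- range(grid$values, na.rm = TRUE)
  if (all(is.finite(rng))) stopifnot(rng[1] >= -1, rng[2] <= 1)
  stopifnot(qc_good >= 0, qc_good <= 1, qc_unclassified >= 0, qc_unclassified <= 1)
  structure(
    list(
      window_start = as.Date(window_start),
      window_end = as.Date(window_start) + window_days, # exclusive
      grid = grid,
      qc_good = qc_good,
      qc_unclassified = qc_unclassified
    ),
    class = "ndwi_composite"
  )
}

#' @export
print.ndwi_composite <- function(x, ...) {
  cat(sprintf(
    "<ndwi_composite [%s, %s): %d x %d cells, qc good %.2f / unclassified %.3f>\n",
    format(x$window_start), format(x$window_end),
    x$grid$nx, x$grid$ny, x$qc_good, x$qc_unclassified
  ))
  invisible(x)
}

#' Quality screen for a composite
#'
#' Usable when at least `min_good` of pixels are good quality and at most
#' `max_unclassified` are unclassified (both bounds inclusive). Failed
#' composites are skipped by the samplers.
#'
#' @param comp An `ndwi_composite`.
#' @param min_good Minimum good-pixel fraction (default 0.92).
#' @param max_unclassified Maximum unclassified fraction (default 0.02).
#' @return Logical.
#' @export
qc_screen <- function(comp, min_good = 0.92, max_unclassified = 0.02) {
  comp$qc_good >= min_good && comp$qc_unclassified <= max_unclassified
}

#' Find the passing composite covering a date
#'
#' @param stack List of `ndwi_composite`s.
#' @param date A Date.
#' @param ... QC thresholds passed to [qc_screen()].
#' @return The composite, or `NULL` if no passing composite covers `date`.
#' @export
composite_for_date <- function(stack, date, ...) {
  idx <- stack_index(stack, ...)
  i <- match_composite(idx, as.numeric(as.Date(date)))
  if (is.na(i)) NULL else stack[[i]]
}

# Numeric window bounds and QC flags of a stack, computed once per
# sampling pass; dates are compared as day numbers.
stack_index <- function(stack, ...) {
  list(
    starts = vapply(stack, function(c) as.numeric(c$window_start), 0),
    ends = vapply(stack, function(c) as.numeric(c$window_end), 0),
    pass = vapply(stack, qc_screen, TRUE, ...)
  )
}

match_composite <- function(idx, day_num) {
  which(idx$pass & idx$starts <= day_num & day_num < idx$ends)[1]
}

#' Daily mean NDWI at a set of positions
#'
#' Nearest-cell lookup (per-pixel index semantics; interpolating across a
#' land/water boundary is not meaningful) at each position from the
#' composite covering `date`; the mean over positions, dropping missing
#' cells. Positions outside the raster extent are dropped with a warning.
#'
#' @param x,y Planar positions (metres, same projection as the rasters).
#' @param date The sample date.
#' @param stack List of `ndwi_composite`s.
#' @param .index Precomputed window index (internal; built automatically).
#' @return The daily mean (scalar), or `NA` when no passing composite
#'   covers the date or every cell is missing.
#' @export
sample_daily_mean <- function(x, y, date, stack, .index = NULL) {
  if (is.null(.index)) .index <- stack_index(stack)
  i <- match_composite(.index, as.numeric(as.Date(date)))
  if (is.na(i)) {
    return(NA_real_)
  }
  comp <- stack[[i]]
  v <- grid_lookup(comp$grid, x, y)
  outside <- attr(v, "outside")
  if (any(outside)) {
    warning(sum(outside), " position(s) outside raster extent dropped")
  }
  v <- v[!outside & !is.na(v)]
  if (length(v) == 0) {
    return(NA_real_)
  }
  mean(v)
}

#' Read a directory of NDWI composites
#'
#' Expects the layout written by the simulation driver: one `.asc` grid
#' per composite plus an `index.json` listing window start dates, QC
#' fractions and the projection origin.
#'
#' @param path Directory containing `index.json` and the `.asc` rasters.
#' @return A list of `ndwi_composite`s with a `proj` attribute.
#' @export
read_composite_dir <- function(path) {
  idx <- jsonlite::read_json(file.path(path, "index.json"))
  stack <- lapply(idx$composites, function(m) {
    ndwi_composite(
      as.Date(m$window_start),
      read_ascii_grid(file.path(path, m$file)),
      qc_good = m$qc_good,
      qc_unclassified = m$qc_unclassified
    )
  })
  attr(stack, "proj") <- local_projection(idx$proj$lon0, idx$proj$lat0)
  stack
}

#' Phase-labelled NDWI samples for one residence area
#'
#' Emits one row per bird-day and phase:
#' \describe{
#'   \item{presence}{each occupied day, sampled at that day's own fixes;}
#'   \item{post_abandonment}{each of the 7 days after `end_date` (only for
#'     abandoned areas), sampled at the *occupancy-period fix locations* —
#'     the bird is gone, so the occupied ground is re-evaluated on the
#'     later composites;}
#'   \item{pre_abandonment_week}{presence samples restricted to the final
#'     7 occupied days;}
#'   \item{post_arrival_week}{presence samples restricted to the first 7
#'     occupied days.}
#' }
#' Areas occupied fewer than 7 days use all their days for the week
#' phases. Days without a QC-passing composite are skipped and counted in
#' the `skipped_days` attribute.
#'
#' @param area One row of a segmentation `areas` tibble.
#' @param stack List of `ndwi_composite`s (planar coordinates must share
#'   the segmentation projection).
#' @param year Grouping year recorded on the rows (defaults to the
#'   calendar year of the area's start date — for an October-December
#'   analysis window this is the study season).
#' @param .index Precomputed window index (internal; built automatically).
#' @return A tibble: `bird_id`, `date`, `area_id`, `year`, `phase`,
#'   `daily_mean_ndwi`.
#' @export
phase_samples <- function(area, stack, year = NULL, .index = NULL) {
  days <- sort(area$days[[1]])
  fx <- area$fix_rows[[1]]
  fx_x <- fx$x
  fx_y <- fx$y
  fx_day <- as.numeric(fx$date)
  if (is.null(.index)) .index <- stack_index(stack)
  if (is.null(year)) year <- as.integer(format(area$start_date, "%Y"))
  rows <- list()
  skipped <- 0L

  pres_vals <- vapply(seq_along(days), function(j) {
    sel <- fx_day == as.numeric(days[j])
    suppressWarnings(sample_daily_mean(fx_x[sel], fx_y[sel], days[j], stack, .index = .index))
  }, 0)
  ok <- !is.na(pres_vals)
  skipped <- skipped + sum(!ok)
  add <- function(dates, values, phase) {
    if (length(dates) == 0) {
      return(NULL)
    }
    tibble::tibble(
      bird_id = area$bird_id, date = as.Date(dates), area_id = area$area_id,
      year = year, phase = phase, daily_mean_ndwi = values
    )
  }
  rows$presence <- add(days[ok], pres_vals[ok], "presence")

  k <- min(7L, length(days))
  pre_idx <- utils::tail(seq_along(days), k)
  arr_idx <- utils::head(seq_along(days), k)
  rows$pre <- add(
    days[pre_idx][ok[pre_idx]], pres_vals[pre_idx][ok[pre_idx]],
    "pre_abandonment_week"
  )
  rows$arr <- add(
    days[arr_idx][ok[arr_idx]], pres_vals[arr_idx][ok[arr_idx]],
    "post_arrival_week"
  )

  if (isTRUE(area$abandoned)) {
    post_dates <- area$end_date + 1:7
    post_vals <- vapply(seq_along(post_dates), function(j) {
      suppressWarnings(sample_daily_mean(fx_x, fx_y, post_dates[j], stack, .index = .index))
    }, 0)
    pok <- !is.na(post_vals)
    skipped <- skipped + sum(!pok)
    rows$post <- add(post_dates[pok], post_vals[pok], "post_abandonment")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_days") <- skipped
  out
}

#' Phase samples for every area of a segmentation
#'
#' @param seg A `segmentation` object.
#' @param stack List of `ndwi_composite`s.
#' @param year Optional grouping year for all areas (default: per-area
#'   calendar year of the start date).
#' @return Row-bound tibble of [phase_samples()] results, with attribute
#'   `skipped_days`.
#' @export
phase_samples_all <- function(seg, stack, year = NULL) {
  n <- nrow(seg$areas)
  out <- vector("list", n)
  skipped <- 0L
  idx <- stack_index(stack)
  for (i in seq_len(n)) {
    s <- phase_samples(seg$areas[i, ], stack, year = year, .index = idx)
    skipped <- skipped + attr(s, "skipped_days")
    out[[i]] <- s
  }
  res <- dplyr::bind_rows(out)
  attr(res, "skipped_days") <- skipped
  res
}
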