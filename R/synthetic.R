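# Synthetic trajectories and NDWI raster time series with known ground
# truth. The generator emulates the study conditions: hourly fixes
# 06:00-18:00 (+02:00), multi-day stays (geometric durations, mean 14 d,
# minimum 2 d) around centroids punctuated by >threshold relocations, an
# October-December analysis season, 8-day / 500 m NDWI composites with a
# baseline near -0.5, and a per-area drying/wetting trend applied after
# each scheduled abandonment.

#' Simulation configuration
#'
#' Defaults are anchored to the field situation the pipeline targets:
#' five birds, October-December seasons, 13 fixes/day, 300 m within-area
#' scatter, mean stay of 14 days (minimum 2), relocation jumps of 8-30 km
#' (safely above a ~3 km Moving-Day threshold), 500 m / 8-day rasters with
#' baseline NDWI -0.5 (birds sit on relatively dry ground), and random
#' intercept scatter across birds, areas and years.
#'
#' @param n_birds Number of birds.
#' @param years Integer vector of season years (October of each).
#' @param season_start_md,season_end_md Month-day of the season bounds.
#' @param fix_hours Hours of day with a fix (default 6:18, i.e. 13/day).
#' @param scatter_m SD of isotropic within-area fix scatter (metres).
#' @param stay_mean_days,stay_min_days Stay-duration distribution:
#'   `stay_min_days` + geometric, with overall mean `stay_mean_days`.
#' @param jump_km_range Uniform range of relocation distances (km).
#' @param range_km Radius (km) of the disc around each bird's home centre
#'   that relocations must stay inside.
#' @param home_spread_km Radius (km) of the disc around the origin in
#'   which bird home centres are placed.
#' @param cell_m,window_days Raster geometry.
#' @param baseline_ndwi Mean NDWI of the landscape.
#' @param noise_sd SD of white spatial noise per cell and window.
#' @param delta Per-area NDWI trend applied to the area's footprint from
#'   the composite containing its abandonment onward (< 0 drying, > 0
#'   wetting).
#' @param footprint_m Radius of an area's raster footprint (metres).
#' @param sd_bird,sd_area,sd_year SDs of random intercepts added to the
#'   NDWI field (bird and area on the footprint, year on the whole
#'   landscape).
#' @param origin Named vector `c(lon = , lat = )` of the study origin.
#' @param fail_qc_windows Integer indices of composite windows (within
#'   each year) forced to fail QC, for propagation tests.
#' @param seed RNG seed (integer; never global state — the generator
#'   restores the caller's RNG).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_birds = 5,
                       years = 2015,
                       season_start_md = "10-01",
                       season_end_md = "12-31",
                       fix_hours = 6:18,
                       scatter_m = 300,
                       stay_mean_days = 14,
                       stay_min_days = 2,
                       jump_km_range = c(8, 30),
                       range_km = 35,
                       home_spread_km = 25,
                       cell_m = 500,
                       window_days = 8,
                       baseline_ndwi = -0.5,
                       noise_sd = 0.06,
                       delta = 0,
                       footprint_m = 1200,
                       sd_bird = 0.05,
                       sd_area = 0.06,
                       sd_year = 0.02,
                       origin = c(lon = 30.2, lat = -12.0),
                       fail_qc_windows = integer(),
                       seed = 1) {
  cfg <- list(
    n_birds = n_birds, years = as.integer(years),
    season_start_md = season_start_md, season_end_md = season_end_md,
    fix_hours = fix_hours, scatter_m = scatter_m,
    stay_mean_days = stay_mean_days, stay_min_days = stay_min_days,
    jump_km_range = jump_km_range, range_km = range_km,
    home_spread_km = home_spread_km,
    cell_m = cell_m, window_days = window_days,
    baseline_ndwi = baseline_ndwi, noise_sd = noise_sd, delta = delta,
    footprint_m = footprint_m,
    sd_bird = sd_bird, sd_area = sd_area, sd_year = sd_year,
    origin = origin, fail_qc_windows = as.integer(fail_qc_windows),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_birds >= 0, cfg$scatter_m >= 0, cfg$noise_sd >= 0,
    cfg$sd_bird >= 0, cfg$sd_area >= 0, cfg$sd_year >= 0,
    cfg$stay_min_days >= 2, cfg$stay_mean_days >= cfg$stay_min_days,
    cfg$jump_km_range[1] > 3, # relocations must exceed the moving threshold
    diff(cfg$jump_km_range) >= 0,
    abs(cfg$baseline_ndwi) <= 1
  )
  structure(cfg, class = "sim_config")
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate GPS trajectories with known structure
#'
#' Each bird gets a home centre near the origin; within the season it
#' alternates multi-day stays (fixes scattered isotropically about the
#' stay centroid) with single relocation days on which the centroid jumps
#' by a uniform random distance in a uniform random bearing (resampled
#' until it stays inside the bird's range disc). On a relocation day the
#' morning fixes sit at the old centroid and the afternoon fixes at the
#' new one, so the day's displacement equals the jump. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `fixes` (tibble), `truth` (list with `areas`,
#'   `moving_days`, `re_bird`, `re_year`, `proj`, `cfg`).
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  proj <- local_projection(cfg$origin[["lon"]], cfg$origin[["lat"]])
  with_local_seed(cfg$seed, {
    birds <- sprintf("B%02d", seq_len(cfg$n_birds))
    re_bird <- stats::setNames(stats::rnorm(cfg$n_birds, 0, cfg$sd_bird), birds)
    re_year <- stats::setNames(stats::rnorm(length(cfg$years), 0, cfg$sd_year),
      as.character(cfg$years))
    # geometric tail above the minimum: mean = min + (1 - p) / p
    p_geom <- 1 / (1 + cfg$stay_mean_days - cfg$stay_min_days)

    fix_rows <- list()
    area_rows <- list()
    moving_rows <- list()
    for (b in birds) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- cfg$home_spread_km * 1000 * sqrt(stats::runif(1))
      home <- c(rad * cos(ang), rad * sin(ang))
      for (yi in seq_along(cfg$years)) {
        yr <- cfg$years[yi]
        d0 <- as.Date(sprintf("%d-%s", yr, cfg$season_start_md))
        d1 <- as.Date(sprintf("%d-%s", yr, cfg$season_end_md))
        centroid <- home + stats::rnorm(2, 0, 2000)
        day <- d0
        seg_start <- d0
        area_re <- stats::rnorm(1, 0, cfg$sd_area)
        stay_left <- cfg$stay_min_days + stats::rgeom(1, p_geom)
        epoch0 <- as.numeric(as.POSIXct(paste(format(d0), "00:00:00"), tz = HM_TZ))
        while (day <= d1) {
          if (stay_left > 0) {
            fix_rows[[length(fix_rows) + 1]] <-
              day_fixes(b, day, d0, epoch0, centroid, centroid, cfg, moving = FALSE)
            stay_left <- stay_left - 1
            if (stay_left == 0 || day == d1) {
              # close the stay
              area_rows[[length(area_rows) + 1]] <- tibble::tibble(
                bird_id = b, year = yr,
                start_date = seg_start, end_date = day,
                cx = centroid[1], cy = centroid[2],
                area_re = area_re, delta = cfg$delta,
                abandoned = day < d1
              )
            }
          } else {
            # relocation day
            moving_rows[[length(moving_rows) + 1]] <- tibble::tibble(bird_id = b, date = day)
            new_centroid <- draw_jump(centroid, home, cfg)
            fix_rows[[length(fix_rows) + 1]] <-
              day_fixes(b, day, d0, epoch0, centroid, new_centroid, cfg, moving = TRUE)
            centroid <- new_centroid
            seg_start <- day + 1
            area_re <- stats::rnorm(1, 0, cfg$sd_area)
            stay_left <- cfg$stay_min_days + stats::rgeom(1, p_geom)
          }
          day <- day + 1
        }
      }
    }
    m <- do.call(rbind, lapply(fix_rows, `[[`, "m"))
    ll <- unproject_xy(proj, m[, 2], m[, 3])
    fixes <- tibble::tibble(
      bird_id = rep(
        vapply(fix_rows, `[[`, "", "bird"),
        vapply(fix_rows, function(r) nrow(r$m), 0L)
      ),
      timestamp = as.POSIXct(m[, 1], tz = HM_TZ, origin = "1970-01-01"),
      lon = ll$lon,
      lat = ll$lat
    )
    areas <- dplyr::bind_rows(area_rows)
    if (nrow(areas) > 0) {
      # a stay truncated by the season end to a single day cannot be an Area
      areas <- areas[as.integer(areas$end_date - areas$start_date) + 1L >= 2L, , drop = FALSE]
    }
    list(
      fixes = fixes,
      truth = list(
        areas = areas,
        moving_days = dplyr::bind_rows(moving_rows),
        re_bird = re_bird,
        re_year = re_year,
        proj = proj,
        cfg = cfg
      )
    )
  })
}

draw_jump <- function(centroid, home, cfg) {
  repeat {
    bearing <- stats::runif(1, 0, 2 * pi)
    dist_m <- stats::runif(1, cfg$jump_km_range[1], cfg$jump_km_range[2]) * 1000
    cand <- centroid + dist_m * c(cos(bearing), sin(bearing))
    if (sqrt(sum((cand - home)^2)) <= cfg$range_km * 1000) {
      return(cand)
    }
  }
}

# One day of fixes as a numeric matrix (epoch seconds, x, y); timestamps
# and lon/lat are materialised once for the whole track, which keeps the
# per-day cost to the random draws.
day_fixes <- function(bird, day, d0, epoch0, centroid_am, centroid_pm, cfg, moving) {
  hrs <- cfg$fix_hours
  n <- length(hrs)
  cents <- if (moving) {
    split_at <- ceiling(n / 2)
    rbind(
      matrix(centroid_am, nrow = split_at, ncol = 2, byrow = TRUE),
      matrix(centroid_pm, nrow = n - split_at, ncol = 2, byrow = TRUE)
    )
  } else {
    matrix(centroid_am, nrow = n, ncol = 2, byrow = TRUE)
  }
  secs <- epoch0 + as.numeric(day - d0) * 86400 + hrs * 3600
  list(
    bird = bird,
    m = cbind(
      secs,
      cents[, 1] + stats::rnorm(n, 0, cfg$scatter_m),
      cents[, 2] + stats::rnorm(n, 0, cfg$scatter_m)
    )
  )
}

#' Simulate NDWI composites consistent with a simulated track set
#'
#' Per window and cell: baseline + year intercept + white spatial noise;
#' cells inside an area's footprint additionally carry the bird and area
#' intercepts, and — from the first composite whose window contains
#' post-abandonment days onward — the area's trend `delta`. Values are
#' clipped to `[-1, 1]`. Windows listed in `cfg$fail_qc_windows` get
#' failing QC fractions. Deterministic under `cfg$seed` (offset so raster
#' draws are independent of track draws).
#'
#' @param cfg A [sim_config()].
#' @param truth The `truth` element returned by [simulate_tracks()].
#' @return A list of `ndwi_composite`s with attribute `proj`.
#' @export
simulate_rasters <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  areas <- truth$areas
  margin <- cfg$footprint_m + 5000
  if (nrow(areas) > 0) {
    xr <- range(areas$cx) + c(-margin, margin)
    yr <- range(areas$cy) + c(-margin, margin)
  } else {
    xr <- c(-1, 1) * (cfg$home_spread_km * 1000 + margin)
    yr <- xr
  }
  x0 <- floor(xr[1] / cfg$cell_m) * cfg$cell_m
  y0 <- floor(yr[1] / cfg$cell_m) * cfg$cell_m
  nx <- ceiling((xr[2] - x0) / cfg$cell_m)
  ny <- ceiling((yr[2] - y0) / cfg$cell_m)
  cx_cells <- x0 + (seq_len(nx) - 0.5) * cfg$cell_m
  cy_cells <- y0 + (seq_len(ny) - 0.5) * cfg$cell_m

  with_local_seed(cfg$seed + 10000L, {
    stack <- list()
    for (yi in seq_along(cfg$years)) {
      yr_ <- cfg$years[yi]
      d0 <- as.Date(sprintf("%d-%s", yr_, cfg$season_start_md))
      d1 <- as.Date(sprintf("%d-%s", yr_, cfg$season_end_md))
      # extend past the season end so post-abandonment days of the last
      # areas are always covered
      starts <- seq(d0, d1 + 14, by = cfg$window_days)
      ar_y <- areas[areas$year == yr_, , drop = FALSE]
      for (wi in seq_along(starts)) {
        ws <- starts[wi]
        we <- ws + cfg$window_days # exclusive
        vals <- matrix(
          cfg$baseline_ndwi + truth$re_year[[as.character(yr_)]] +
            stats::rnorm(nx * ny, 0, cfg$noise_sd),
          nrow = nx, ncol = ny
        )
        for (ai in seq_len(nrow(ar_y))) {
          a <- ar_y[ai, ]
          ix <- which(abs(cx_cells - a$cx) <= cfg$footprint_m)
          iy <- which(abs(cy_cells - a$cy) <= cfg$footprint_m)
          if (length(ix) == 0 || length(iy) == 0) next
          sel <- as.matrix(expand.grid(ix, iy))
          d2 <- (cx_cells[sel[, 1]] - a$cx)^2 + (cy_cells[sel[, 2]] - a$cy)^2
          sel <- sel[d2 <= cfg$footprint_m^2, , drop = FALSE]
          if (nrow(sel) == 0) next
          eff <- truth$re_bird[[a$bird_id]] + a$area_re
          # delta from the first composite that contains post-abandonment
          # days (window_end is exclusive: last covered date is we - 1)
          if (a$abandoned && (we - 1) > a$end_date) eff <- eff + a$delta
          vals[sel] <- vals[sel] + eff
        }
        vals <- pmin(1, pmax(-1, vals))
        failing <- wi %in% cfg$fail_qc_windows
        stack[[length(stack) + 1]] <- ndwi_composite(
          ws, planar_grid(x0, y0, cfg$cell_m, nx, ny, vals),
          qc_good = if (failing) 0.5 else 0.98,
          qc_unclassified = if (failing) 0.1 else 0.005,
          window_days = cfg$window_days
        )
      }
    }
    attr(stack, "proj") <- truth$proj
    stack
  })
}

#' Ready-made end-to-end fixtures
#'
#' Three presets anchored to the contrasts the pipeline is meant to
#' detect: `"adults"` — abandoned areas dry (delta = -0.05, the direction
#' and size of a -0.52 to -0.57 presence-to-post shift); `"immatures"` —
#' abandoned areas wet (delta = +0.10, a -0.53 to -0.43 shift);
#' `"null"` — no before/after difference (delta = 0), the regime in which
#' the area-selection model should find nothing.
#'
#' @param preset `"adults"`, `"immatures"` or `"null"`.
#' @param seed RNG seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A list: `cfg`, `fixes`, `truth`, `rasters`.
#' @export
end_to_end_fixture <- function(preset = c("adults", "immatures", "null"),
                               seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    adults = list(n_birds = 5, years = 2013:2015, delta = -0.05),
    immatures = list(n_birds = 6, years = 2014:2015, delta = 0.10),
    null = list(n_birds = 6, years = 2014:2015, delta = 0)
  )
  args$seed <- seed
  extra <- list(...)
  args[names(extra)] <- extra
  cfg <- do.call(sim_config, args)
  sim <- simulate_tracks(cfg)
  rasters <- simulate_rasters(cfg, sim$truth)
  list(cfg = cfg, fixes = sim$fixes, truth = sim$truth, rasters = rasters)
}

#' Write simulation ground truth as JSON
#' @param truth The `truth` element of [simulate_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      areas = dplyr::mutate(truth$areas,
        start_date = format(.data$start_date), end_date = format(.data$end_date)
      ),
      moving_days = dplyr::mutate(truth$moving_days, date = format(.data$date)),
      re_bird = as.list(truth$re_bird),
      re_year = as.list(truth$re_year),
      seed = truth$cfg$seed
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
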