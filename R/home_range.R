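# Kernel-density home ranges: reference (href) bandwidth, gridded
# utilisation distribution, isopleth areas, and annual (May-April)
# summaries per bird and age class.

#' Reference bandwidth (href)
#'
#' The ad-hoc bivariate-normal reference bandwidth used by classical
#' home-range software: `h = 0.5 * (sd_x + sd_y) * n^(-1/6)`, with sample
#' standard deviations in metres. Simple and smooth, it over-smooths
#' strongly clumped data — which is why it is reported alongside the
#' estimate so users can compare alternative h choices.
#'
#' @param x,y Planar coordinates in metres (n >= 5).
#' @return Bandwidth in metres.
#' @export
href_bandwidth <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("href needs at least 5 points; supply a fixed bandwidth instead")
  h <- 0.5 * (stats::sd(x) + stats::sd(y)) * n^(-1 / 6)
  if (!is.finite(h) || h <= 0) {
    stop("degenerate point set (zero spread); supply a fixed bandwidth instead")
  }
  h
}

#' Kernel density at arbitrary points
#'
#' Bivariate normal kernel with independent, equal bandwidth per axis:
#' `f(p) = mean_i dnorm(px - xi, sd = h) * dnorm(py - yi, sd = h)`.
#'
#' @param x,y Data coordinates (metres).
#' @param h Bandwidth (metres), > 0.
#' @param at_x,at_y Evaluation points (same length).
#' @return Density values (per m^2).
#' @export
kde_density <- function(x, y, h, at_x, at_y) {
  stopifnot(h > 0, length(at_x) == length(at_y))
  dx <- stats::dnorm(outer(at_x, x, `-`), sd = h)
  dy <- stats::dnorm(outer(at_y, y, `-`), sd = h)
  rowSums(dx * dy) / length(x)
}

#' Gridded kernel utilisation distribution
#'
#' Evaluates the kernel density at the centres of a regular grid that
#' extends at least `pad_h * h` beyond the data bounding box, then
#' normalises so the cell masses sum to one (the discrete utilisation
#' distribution).
#'
#' @param x,y Planar coordinates (metres).
#' @param h Bandwidth (metres), > 0.
#' @param cell_m Cell size (default 500 m).
#' @param pad_h Grid margin in bandwidths (default 3).
#' @return A `planar_grid` whose values are densities (per m^2), with
#'   attribute `h`.
#' @export
kde_grid <- function(x, y, h, cell_m = 500, pad_h = 3) {
  stopifnot(h > 0, cell_m > 0)
  pad <- pad_h * h
  x0 <- floor((min(x) - pad) / cell_m) * cell_m
  y0 <- floor((min(y) - pad) / cell_m) * cell_m
  nx <- ceiling((max(x) + pad - x0) / cell_m)
  ny <- ceiling((max(y) + pad - y0) / cell_m)
  gx <- x0 + (seq_len(nx) - 0.5) * cell_m
  gy <- y0 + (seq_len(ny) - 0.5) * cell_m
  dx <- stats::dnorm(outer(gx, x, `-`), sd = h) # nx x n
  dy <- stats::dnorm(outer(gy, y, `-`), sd = h) # ny x n
  dens <- (dx %*% t(dy)) / length(x)
  dens <- dens / (sum(dens) * cell_m^2) # exact discrete normalisation
  g <- planar_grid(x0, y0, cell_m, nx, ny, dens)
  attr(g, "h") <- h
  g
}

#' Isopleth area of a utilisation distribution
#'
#' Sorts cells by density (descending) and takes the smallest set whose
#' cumulative probability mass reaches `level`; the area is the cell count
#' times the cell area. At tied densities cells are included in index
#' order until the mass is reached, which keeps the area deterministic.
#'
#' @param grid A normalised density `planar_grid` (from [kde_grid()]).
#' @param level Fraction in (0, 1), e.g. 0.95 or 0.50.
#' @return Area in km^2, with attribute `mask` (logical matrix of included
#'   cells) and `mass` (achieved cumulative mass).
#' @export
isopleth_area <- function(grid, level) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must be strictly between 0 and 1")
  }
  v <- as.vector(grid$values)
  mass <- v * grid$cell^2
  ord <- order(-v, seq_along(v))
  cum <- cumsum(mass[ord])
  k <- which(cum >= level * sum(mass))[1]
  if (is.na(k)) k <- length(v)
  mask <- matrix(FALSE, grid$nx, grid$ny)
  mask[ord[seq_len(k)]] <- TRUE
  area <- k * (grid$cell / 1000)^2
  attr(area, "mask") <- mask
  attr(area, "mass") <- cum[k] / sum(mass)
  area
}

# Season-year of a date: years run May -> April, labelled by starting year.
season_year <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  ifelse(m >= 5, y, y - 1L)
}

#' Annual kernel home ranges per bird and season-year
#'
#' One kernel home range per bird and May-to-April season-year with at
#' least `min_fixes` fixes (smaller seasons are skipped and logged in the
#' `skipped` attribute). Each range is fitted in its own local projection
#' about the season's mean coordinate.
#'
#' @param fixes Cleaned fixes tibble.
#' @param age_windows Optional age windows ([assign_age_windows()]);
#'   `NULL` pools into class `"all"`.
#' @param cell_m KDE grid cell size (default 500 m).
#' @param min_fixes Minimum fixes per bird-season (default 30).
#' @param keep_grids Keep the density grids as a list-column (default
#'   FALSE; they are large).
#' @return A tibble: `bird_id`, `season_year`, `age_class`, `n_fixes`,
#'   `href_m`, `area_km2_95`, `area_km2_50` (+ `grid` if requested), with
#'   attribute `skipped`.
#' @export
annual_ranges <- function(fixes, age_windows = NULL, cell_m = 500,
                          min_fixes = 30, keep_grids = FALSE) {
  fx <- fixes
  fx$date <- as.Date(fx$timestamp, tz = HM_TZ)
  fx$season_year <- season_year(fx$date)
  fx$age_class <- if (is.null(age_windows)) {
    "all"
  } else {
    age_class_at(fx$date, age_windows, fx$bird_id)
  }
  fx <- fx[!is.na(fx$age_class), , drop = FALSE]
  keys <- unique(fx[, c("bird_id", "season_year")])
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- fx[fx$bird_id == keys$bird_id[i] & fx$season_year == keys$season_year[i], , drop = FALSE]
    if (nrow(sub) < min_fixes) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        bird_id = keys$bird_id[i], season_year = keys$season_year[i], n_fixes = nrow(sub)
      )
      next
    }
    proj <- local_projection(mean(sub$lon), mean(sub$lat))
    xy <- project_xy(proj, sub$lon, sub$lat)
    h <- href_bandwidth(xy$x, xy$y)
    g <- kde_grid(xy$x, xy$y, h, cell_m = cell_m)
    rows[[length(rows) + 1]] <- tibble::tibble(
      bird_id = keys$bird_id[i],
      season_year = keys$season_year[i],
      age_class = sub$age_class[1],
      n_fixes = nrow(sub),
      href_m = h,
      area_km2_95 = as.numeric(isopleth_area(g, 0.95)),
      area_km2_50 = as.numeric(isopleth_area(g, 0.50)),
      grid = if (keep_grids) list(g) else list(NULL)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_grids && nrow(out) > 0) out$grid <- NULL
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}

#' Class-level summary of annual home ranges
#'
#' @param ranges Output of [annual_ranges()].
#' @return A tibble: `age_class`, `n_ranges`, mean and sample SD of the
#'   95% and 50% isopleth areas.
#' @export
range_summary <- function(ranges) {
  stopifnot(nrow(ranges) > 0)
  ranges |>
    dplyr::group_by(.data$age_class) |>
    dplyr::summarise(
      n_ranges = dplyr::n(),
      mean_km2_95 = mean(.data$area_km2_95),
      sd_km2_95 = dplyr::if_else(dplyr::n() > 1, stats::sd(.data$area_km2_95), 0),
      mean_km2_50 = mean(.data$area_km2_50),
      sd_km2_50 = dplyr::if_else(dplyr::n() > 1, stats::sd(.data$area_km2_50), 0),
      .groups = "drop"
    )
}

#' Cumulative (pooled-fix) home range for a set of birds
#'
#' Pools all fixes (optionally one age class) into a single kernel
#' utilisation distribution — the "cumulative" range used to map the area
#' a tracked population uses.
#'
#' @inheritParams annual_ranges
#' @param class Optional single age class to keep.
#' @return A list: `grid` (`planar_grid`), `proj`, `href_m`,
#'   `area_km2_95`, `area_km2_50`, `n_fixes`.
#' @export
pooled_range <- function(fixes, age_windows = NULL, class = NULL, cell_m = 500) {
  fx <- fixes
  fx$date <- as.Date(fx$timestamp, tz = HM_TZ)
  if (!is.null(class) && !is.null(age_windows)) {
    cls <- age_class_at(fx$date, age_windows, fx$bird_id)
    fx <- fx[!is.na(cls) & cls == class, , drop = FALSE]
  }
  stopifnot(nrow(fx) >= 5)
  proj <- local_projection(mean(fx$lon), mean(fx$lat))
  xy <- project_xy(proj, fx$lon, fx$lat)
  h <- href_bandwidth(xy$x, xy$y)
  g <- kde_grid(xy$x, xy$y, h, cell_m = cell_m)
  list(
    grid = g, proj = proj, href_m = h,
    area_km2_95 = as.numeric(isopleth_area(g, 0.95)),
    area_km2_50 = as.numeric(isopleth_area(g, 0.50)),
    n_fixes = nrow(fx)
  )
}
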