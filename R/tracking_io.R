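# Reading, validating and age-classifying raw GPS tracking data.
#
# Fixes live in a plain tibble (bird_id, timestamp, lon, lat), timestamps in
# a fixed UTC+02:00 offset ("Etc/GMT-2"), the birds' activity clock: the
# loggers record hourly between 06:00 and 18:00 local, and all "day"
# boundaries downstream are local midnight.

#' Timezone used for all fix timestamps (fixed UTC+02:00 offset)
#' @export
HM_TZ <- "Etc/GMT-2"

#' Read GPS fixes from a delimited text file
#'
#' Reads a CSV of GPS fixes, validates coordinates and timestamps, groups
#' by bird and sorts by time. Rows that cannot be used (unparseable
#' timestamp or coordinate, out-of-range lon/lat, duplicated timestamp
#' within a bird) are removed and reported in the `rejects` attribute with
#' a reason column.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named character vector mapping the canonical names
#'   `bird_id`, `timestamp`, `lon`, `lat` to the file's column headers
#'   (Movebank-style headers can be mapped here).
#' @param exclude Optional integer vector of input row numbers to drop
#'   (stands in for manual visual track inspection).
#' @param track_ends Optional named Date vector (names = bird ids): fixes
#'   after a bird's end date — e.g. after presumed death or transmitter
#'   loss — are rejected. Off by default.
#' @return A tibble with columns `bird_id`, `timestamp` (POSIXct, +02:00),
#'   `lon`, `lat`, sorted by bird then time, with attribute `rejects`
#'   (tibble: row, reason).
#' @export
read_fixes <- function(path,
                       column_map = c(
                         bird_id = "bird_id", timestamp = "timestamp",
                         lon = "lon", lat = "lat"
                       ),
                       exclude = NULL,
                       track_ends = NULL) {
  needed <- c("bird_id", "timestamp", "lon", "lat")
  stopifnot(all(needed %in% names(column_map)))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    warning("empty fix file: ", path)
    return(empty_fixes())
  }
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::tibble(
    row = seq_len(nrow(raw)),
    bird_id = as.character(raw[[column_map[["bird_id"]]]]),
    ts_raw = raw[[column_map[["timestamp"]]]],
    lon = suppressWarnings(as.numeric(raw[[column_map[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[column_map[["lat"]]]]))
  )
  df$timestamp <- parse_fix_time(df$ts_raw)

  reasons <- rep(NA_character_, nrow(df))
  if (!is.null(exclude)) reasons[df$row %in% exclude] <- "excluded by user list"
  bad_ts <- is.na(df$timestamp) & is.na(reasons)
  reasons[bad_ts] <- "unparseable timestamp"
  bad_coord <- (is.na(df$lon) | is.na(df$lat)) & is.na(reasons)
  reasons[bad_coord] <- "unparseable coordinate"
  oob <- (!is.na(df$lon) & !is.na(df$lat) &
    (abs(df$lon) > 180 | abs(df$lat) > 90)) & is.na(reasons)
  reasons[oob] <- "coordinate out of range"
  if (!is.null(track_ends)) {
    ends <- as.Date(track_ends[df$bird_id])
    late <- !is.na(ends) & !is.na(df$timestamp) &
      as.Date(df$timestamp, tz = HM_TZ) > ends & is.na(reasons)
    reasons[late] <- "after track end date"
  }

  ok <- df[is.na(reasons), , drop = FALSE]
  ok <- ok[order(ok$bird_id, ok$timestamp, ok$row), , drop = FALSE]
  dup <- duplicated(ok[, c("bird_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) dropped (first kept)")
    reasons[ok$row[dup]] <- "duplicate timestamp"
    ok <- ok[!dup, , drop = FALSE]
  }
  rejects <- tibble::tibble(
    row = df$row[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  fixes <- tibble::tibble(
    bird_id = ok$bird_id, timestamp = ok$timestamp, lon = ok$lon, lat = ok$lat
  )
  attr(fixes, "rejects") <- rejects
  fixes
}

empty_fixes <- function() {
  fixes <- tibble::tibble(
    bird_id = character(),
    timestamp = as.POSIXct(character(), tz = HM_TZ),
    lon = numeric(), lat = numeric()
  )
  attr(fixes, "rejects") <- tibble::tibble(row = integer(), reason = character())
  fixes
}

# ISO-8601 with or without offset/'T'; result is expressed in fixed +02:00.
parse_fix_time <- function(x) {
  x <- gsub("T", " ", x)
  has_offset <- grepl("[+-][0-9]{2}:?[0-9]{2}$", x) | grepl("Z$", x)
  out <- rep(as.POSIXct(NA, tz = HM_TZ), length(x))
  if (any(has_offset, na.rm = TRUE)) {
    idx <- which(has_offset)
    v <- as.POSIXct(gsub("Z$", " +0000", gsub("([+-][0-9]{2}):([0-9]{2})$", " \\1\\2", x[idx])),
      format = "%Y-%m-%d %H:%M:%S %z", tz = HM_TZ
    )
    out[idx] <- v
  }
  idx <- which(!has_offset)
  if (length(idx) > 0) {
    v <- as.POSIXct(x[idx], format = "%Y-%m-%d %H:%M:%S", tz = HM_TZ)
    # allow date-hour without seconds
    v2 <- as.POSIXct(x[idx], format = "%Y-%m-%d %H:%M", tz = HM_TZ)
    v[is.na(v)] <- v2[is.na(v)]
    out[idx] <- v
  }
  out
}

#' Write fixes back to CSV
#'
#' Timestamps are written as ISO-8601 with explicit offset so a
#' read/write/read round trip preserves every fix exactly.
#'
#' @param fixes A fixes tibble (see [read_fixes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- tibble::tibble(
    bird_id = fixes$bird_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S+02:00", tz = HM_TZ),
    lon = fixes$lon,
    lat = fixes$lat
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write the rejected rows of a read, with reasons
#' @param fixes A fixes tibble carrying a `rejects` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(fixes, path) {
  rej <- attr(fixes, "rejects")
  if (is.null(rej)) rej <- tibble::tibble(row = integer(), reason = character())
  readr::write_csv(rej, path)
  invisible(path)
}

#' Remove speed outliers from a trajectory
#'
#' Sequential greedy filter: walking forward in time within each bird, a fix
#' is removed when the great-circle speed from the last *retained* fix
#' exceeds `max_kmh`. This makes the paper-style rule ("more than 150 km/h
#' between two consecutive hourly locations") deterministic and
#' order-stable, and is idempotent.
#'
#' @param fixes A fixes tibble.
#' @param max_kmh Speed threshold in km/h (default 150).
#' @return A list with `fixes` (retained) and `removed` (dropped fixes).
#' @export
filter_speed_outliers <- function(fixes, max_kmh = 150) {
  stopifnot(max_kmh > 0)
  keep <- rep(TRUE, nrow(fixes))
  for (b in unique(fixes$bird_id)) {
    idx <- which(fixes$bird_id == b)
    if (length(idx) < 2) next
    # removing the first offender and re-checking the remainder is exactly
    # the left-to-right greedy walk, but lets each check be one vectorised
    # haversine call over all consecutive retained pairs
    retained <- idx
    repeat {
      a <- retained[-length(retained)]
      z <- retained[-1]
      dt_h <- as.numeric(fixes$timestamp[z] - fixes$timestamp[a], units = "hours")
      d_km <- great_circle_km(fixes$lon[a], fixes$lat[a], fixes$lon[z], fixes$lat[z])
      speed <- ifelse(dt_h > 0, d_km / dt_h, Inf) # non-increasing time: drop
      bad <- which(speed > max_kmh)
      if (length(bad) == 0) break
      retained <- retained[-(bad[1] + 1)]
      if (length(retained) < 2) break
    }
    keep[setdiff(idx, retained)] <- FALSE
  }
  list(
    fixes = fixes[keep, , drop = FALSE],
    removed = fixes[!keep, , drop = FALSE]
  )
}

#' Assign age-class windows to a tracked bird
#'
#' Birds tagged as juveniles are juvenile until the first 1 May after
#' tagging (the start of the next breeding season), immature for the two
#' following May-to-May years, and adult from then on. A bird tagged as an
#' adult is adult throughout. Windows are truncated to the tracking span,
#' so they partition it exactly.
#'
#' @param bird_id Bird identifier.
#' @param tagging_date Date of tag deployment.
#' @param end_date Last tracked date.
#' @param tagging_class `"juvenile"` or `"adult"`.
#' @return A tibble with columns `bird_id`, `class`, `start_date`,
#'   `end_date` (contiguous, non-overlapping).
#' @export
assign_age_windows <- function(bird_id, tagging_date, end_date,
                               tagging_class = c("juvenile", "adult")) {
  tagging_class <- match.arg(tagging_class)
  tagging_date <- as.Date(tagging_date)
  end_date <- as.Date(end_date)
  stopifnot(end_date >= tagging_date)
  if (tagging_class == "adult") {
    return(tibble::tibble(
      bird_id = bird_id, class = "adult",
      start_date = tagging_date, end_date = end_date
    ))
  }
  first_may <- next_may1(tagging_date)
  bounds <- c(
    juvenile = first_may,
    immature = seq(first_may, by = "2 years", length.out = 2)[2]
  )
  win <- tibble::tibble(
    bird_id = bird_id,
    class = c("juvenile", "immature", "adult"),
    start_date = c(tagging_date, bounds[["juvenile"]], bounds[["immature"]]),
    end_date = c(bounds[["juvenile"]] - 1, bounds[["immature"]] - 1, end_date)
  )
  win <- win[win$start_date <= end_date, , drop = FALSE]
  win$end_date <- pmin(win$end_date, end_date)
  win
}

# First 1 May strictly after `date`.
next_may1 <- function(date) {
  y <- as.integer(format(date, "%Y"))
  cand <- as.Date(sprintf("%d-05-01", y))
  if (cand > date) cand else as.Date(sprintf("%d-05-01", y + 1))
}

#' Age class for each of a vector of dates
#'
#' @param dates Date vector.
#' @param windows Age-window tibble from [assign_age_windows()] (possibly
#'   several birds row-bound).
#' @param bird_id Bird identifiers matching `dates` (recycled if length 1).
#' @return Character vector of classes, `NA` outside any window.
#' @export
age_class_at <- function(dates, windows, bird_id) {
  dates <- as.Date(dates)
  if (length(bird_id) == 1) bird_id <- rep(bird_id, length(dates))
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(windows))) {
    hit <- bird_id == windows$bird_id[i] &
      dates >= windows$start_date[i] & dates <= windows$end_date[i]
    out[hit] <- windows$class[i]
  }
  out
}
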