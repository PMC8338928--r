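test_that("read_fixes groups by bird, sorts by time, and reports rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "bird_id,timestamp,lon,lat",
    "A,2015-10-01T08:00:00+02:00,30.20,-12.00",
    "B,2015-10-01T06:00:00+02:00,30.25,-12.05",
    "A,2015-10-01T06:00:00+02:00,30.21,-12.01",
    "B,2015-10-01T07:00:00+02:00,30.26,-12.06",
    "A,2015-10-01T07:00:00+02:00,30.22,-12.02",
    "C,2015-10-01T06:00:00+02:00,30.20,95.0",
    "C,not-a-time,30.20,-12.00"
  ), path)
  fx <- read_fixes(path)
  expect_equal(nrow(fx), 5)
  expect_equal(sort(unique(fx$bird_id)), c("A", "B"))
  a <- fx[fx$bird_id == "A", ]
  expect_equal(nrow(a), 3)
  expect_true(all(diff(a$timestamp) > 0))
  expect_equal(format(a$timestamp[1], "%H"), "06")
  rej <- attr(fx, "rejects")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("coordinate out of range", "unparseable timestamp"))
})

test_that("read_fixes handles empty files, missing columns, duplicates and column maps", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("bird_id,timestamp,lon,lat", empty)
  expect_warning(fx <- read_fixes(empty), "empty")
  expect_equal(nrow(fx), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bird_id,when,lon,lat", "A,2015-10-01 06:00:00,30,-12"), bad)
  expect_error(read_fixes(bad), "missing mandatory column")

  mapped <- read_fixes(bad, column_map = c(
    bird_id = "bird_id", timestamp = "when", lon = "lon", lat = "lat"
  ))
  expect_equal(nrow(mapped), 1)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "bird_id,timestamp,lon,lat",
    "A,2015-10-01 06:00:00,30.0,-12.0",
    "A,2015-10-01 06:00:00,30.5,-12.5"
  ), dup)
  expect_warning(fx2 <- read_fixes(dup), "duplicate")
  expect_equal(nrow(fx2), 1)
  expect_equal(fx2$lon, 30.0) # first kept
})

test_that("a configured track end date rejects later fixes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "bird_id,timestamp,lon,lat",
    "A,2015-10-01 06:00:00,30.0,-12.0",
    "A,2015-10-05 06:00:00,30.0,-12.0",
    "B,2015-10-05 06:00:00,30.1,-12.1"
  ), path)
  fx <- read_fixes(path, track_ends = c(A = as.Date("2015-10-03")))
  expect_equal(nrow(fx), 2)
  expect_equal(attr(fx, "rejects")$reason, "after track end date")
  # off by default
  expect_equal(nrow(read_fixes(path)), 3)
})

test_that("write/read round trip preserves fixes exactly", {
  fx <- traj_from_centroids("A", "2015-10-01", cx = c(0, 500, 20000), cy = c(0, -300, 5000), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(fx, path)
  back <- read_fixes(path)
  expect_identical(back$bird_id, fx$bird_id)
  expect_identical(back$lon, fx$lon)
  expect_identical(back$lat, fx$lat)
  expect_true(all(as.numeric(back$timestamp) == as.numeric(fx$timestamp)))
})

test_that("speed filter follows the sequential greedy rule", {
  # two fixes an hour apart: 10 km keeps both, 200 km drops the second
  deg10 <- 10 / 111.19493
  deg200 <- 200 / 111.19493
  near <- fixes_at("A", "2015-10-01", lon = c(30, 30 + deg10), lat = c(0, 0))
  out <- filter_speed_outliers(near)
  expect_equal(nrow(out$fixes), 2)

  far <- fixes_at("A", "2015-10-01", lon = c(30, 30 + deg200), lat = c(0, 0))
  out <- filter_speed_outliers(far)
  expect_equal(nrow(out$fixes), 1)
  expect_equal(nrow(out$removed), 1)

  # 0, 160, 161 km at 0, 1, 2 h: the middle fix trips the filter (160 km/h),
  # the third survives against the first retained fix (161 km / 2 h)
  seq3 <- fixes_at("A", "2015-10-01",
    lon = 30 + c(0, 160, 161) / 111.19493, lat = c(0, 0, 0)
  )
  out <- filter_speed_outliers(seq3)
  expect_equal(nrow(out$fixes), 2)
  expect_equal(out$removed$timestamp, seq3$timestamp[2])
})

test_that("speed filter is idempotent and keeps single-fix trajectories", {
  one <- fixes_at("A", "2015-10-01", lon = 30, lat = -12)
  expect_equal(nrow(filter_speed_outliers(one)$fixes), 1)

  fx <- withr::with_seed(5, {
    base <- traj_from_centroids("A", "2015-10-01", cx = rep(0, 5), cy = rep(0, 5))
    # inject two wild outliers
    base$lon[c(10, 40)] <- base$lon[c(10, 40)] + 3
    base
  })
  first <- filter_speed_outliers(fx)
  expect_gt(nrow(first$removed), 0)
  second <- filter_speed_outliers(first$fixes)
  expect_equal(nrow(second$removed), 0)
  expect_identical(second$fixes, first$fixes)
})

test_that("age windows follow the May-1st calendar walk and partition the span", {
  w <- assign_age_windows("521", "2013-08-03", "2018-05-02", "juvenile")
  expect_equal(w$class, c("juvenile", "immature", "adult"))
  expect_equal(w$start_date, as.Date(c("2013-08-03", "2014-05-01", "2016-05-01")))
  expect_equal(w$end_date, as.Date(c("2014-04-30", "2016-04-30", "2018-05-02")))

  ad <- assign_age_windows("517", "2013-07-29", "2017-08-15", "adult")
  expect_equal(nrow(ad), 1)
  expect_equal(ad$class, "adult")

  # dies before the first 1 May: single truncated juvenile window
  juv <- assign_age_windows("510", "2013-08-30", "2013-11-14", "juvenile")
  expect_equal(nrow(juv), 1)
  expect_equal(juv$class, "juvenile")
  expect_equal(juv$end_date, as.Date("2013-11-14"))

  # property: windows are contiguous and cover the span exactly
  for (tag in as.Date(c("2012-09-09", "2014-04-30", "2014-05-01", "2011-12-03"))) {
    end <- tag + 2000
    w <- assign_age_windows("X", tag, end, "juvenile")
    expect_equal(w$start_date[1], tag)
    expect_equal(w$end_date[nrow(w)], end)
    if (nrow(w) > 1) {
      expect_equal(w$start_date[-1], w$end_date[-nrow(w)] + 1)
    }
  }
})

test_that("age_class_at maps dates through windows", {
  w <- assign_age_windows("521", "2013-08-03", "2018-05-02", "juvenile")
  cls <- age_class_at(
    as.Date(c("2013-09-01", "2014-05-01", "2016-04-30", "2016-05-01", "2019-01-01")),
    w, "521"
  )
  expect_equal(cls, c("juvenile", "immature", "immature", "adult", NA))
})
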