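two_patch_traj <- function(dist_m = 20000, seed = 2) {
  # 5 staying days at A, 1 moving day (morning A, afternoon B), 4 staying
  # days at B; 300 m scatter
  cx <- c(rep(0, 5), NA, rep(dist_m, 4))
  fx <- list()
  withr::with_seed(seed, {
    for (i in seq_along(cx)) {
      day <- as.Date("2015-10-01") + i - 1
      if (is.na(cx[i])) {
        x <- c(rnorm(7, 0, 300), rnorm(6, dist_m, 300))
      } else {
        x <- rnorm(13, cx[i], 300)
      }
      y <- rnorm(13, 0, 300)
      ll <- unproject_xy(TEST_PROJ, x, y)
      fx[[i]] <- fixes_at("A", day, ll$lon, ll$lat)
    }
  })
  dplyr::bind_rows(fx)
}

test_that("distinct patches yield two areas; identical patches merge to one", {
  fx <- two_patch_traj(20000)
  d <- daily_movements(fx)
  seg <- segment_areas(d, fx, threshold = 3, proj = TEST_PROJ)
  expect_equal(nrow(seg$areas), 2)
  expect_equal(seg$areas$duration_days, c(5L, 4L))
  expect_equal(nrow(seg$moving_days), 1)
  expect_false(any(seg$merge_log$overlap))

  # same construction with B == A: the two candidate MCPs overlap -> merged
  fx0 <- two_patch_traj(0)
  d0 <- daily_movements(fx0)
  seg0 <- segment_areas(d0, fx0, threshold = 3, proj = TEST_PROJ)
  expect_equal(nrow(seg0$areas), 1)
  expect_equal(seg0$areas$start_date, as.Date("2015-10-01"))
  expect_equal(seg0$areas$end_date, as.Date("2015-10-10"))
})

test_that("single staying days between moving days are discarded", {
  # stay 3 days, move, stay 1 day, move, stay 3 days
  cents <- c(rep(0, 3), NA, rep(30000, 1), NA, rep(60000, 3))
  fx <- list()
  withr::with_seed(4, {
    for (i in seq_along(cents)) {
      day <- as.Date("2015-10-01") + i - 1
      cx <- if (is.na(cents[i])) {
        prev <- cents[max(which(!is.na(cents[seq_len(i - 1)])))]
        nxt <- cents[i + min(which(!is.na(cents[(i + 1):length(cents)])))]
        c(rep(prev, 7), rep(nxt, 6))
      } else {
        rep(cents[i], 13)
      }
      ll <- unproject_xy(TEST_PROJ, cx + rnorm(13, 0, 200), rnorm(13, 0, 200))
      fx[[i]] <- fixes_at("A", day, ll$lon, ll$lat)
    }
  })
  fx <- dplyr::bind_rows(fx)
  d <- daily_movements(fx)
  seg <- segment_areas(d, fx, threshold = 3, proj = TEST_PROJ)
  expect_equal(nrow(seg$areas), 2)
  expect_equal(nrow(seg$discarded_runs), 1)
  expect_equal(seg$discarded_runs$n_days, 1L)
})

test_that("segmentation matches the brute-force oracle on short trajectories", {
  withr::with_seed(31, {
    for (rep in 1:12) {
      # random stay/move pattern over <= 15 days; patch spacing sometimes
      # small enough that MCPs overlap and runs must merge
      n_days <- sample(8:15, 1)
      spacing <- sample(c(700, 1500, 12000), 1)
      centroid <- c(0, 0)
      cx <- cy <- numeric(n_days)
      moving <- logical(n_days)
      for (i in seq_len(n_days)) {
        if (i > 1 && runif(1) < 0.3) {
          moving[i] <- TRUE
          centroid <- centroid + c(spacing, 0)
        }
        cx[i] <- centroid[1]
        cy[i] <- centroid[2]
      }
      fx <- list()
      for (i in seq_len(n_days)) {
        x <- rnorm(13, cx[i], 250)
        y <- rnorm(13, cy[i], 250)
        if (moving[i]) x[1:6] <- rnorm(6, cx[i] - spacing, 250)
        ll <- unproject_xy(TEST_PROJ, x, y)
        fx[[i]] <- fixes_at("A", as.Date("2015-10-01") + i - 1, ll$lon, ll$lat)
      }
      fx <- dplyr::bind_rows(fx)
      d <- daily_movements(fx)
      thr <- max(1, spacing / 2000) # km; between scatter and jump scale
      seg <- segment_areas(d, fx, threshold = thr, proj = TEST_PROJ)

      fxp <- fx
      fxp$date <- as.Date(fxp$timestamp, tz = HM_TZ)
      xy <- project_xy(TEST_PROJ, fxp$lon, fxp$lat)
      fxp$x <- xy$x
      fxp$y <- xy$y
      oracle <- segment_oracle(d, fxp, thr)

      expect_equal(nrow(seg$areas), length(oracle), info = sprintf("rep %d", rep))
      if (length(oracle) > 0) {
        expect_equal(
          unname(lapply(seg$areas$days, as.character)),
          unname(lapply(oracle, function(s) as.character(s$days))),
          info = sprintf("rep %d", rep)
        )
      }
    }
  })
})

test_that("segmentation is invariant to fix order within a day", {
  fx <- two_patch_traj(20000)
  d <- daily_movements(fx)
  seg1 <- segment_areas(d, fx, threshold = 3, proj = TEST_PROJ)
  shuffled <- withr::with_seed(8, fx[sample(nrow(fx)), ])
  seg2 <- segment_areas(daily_movements(shuffled), shuffled, threshold = 3, proj = TEST_PROJ)
  expect_equal(seg1$areas$start_date, seg2$areas$start_date)
  expect_equal(seg1$areas$end_date, seg2$areas$end_date)
  expect_equal(seg1$areas$n_fixes, seg2$areas$n_fixes)
})

test_that("raising the threshold never increases the number of moving days", {
  sim <- simulate_tracks(sim_config(n_birds = 2, years = 2015, seed = 9))
  d <- daily_movements(sim$fixes)
  counts <- vapply(c(1, 2, 3, 5, 10), function(t) {
    nrow(segment_areas(d, sim$fixes, threshold = t, proj = sim$truth$proj)$moving_days)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("stay durations use the sample standard deviation", {
  areas <- tibble::tibble(
    bird_id = c("A", "A"), duration_days = c(2L, 4L),
    start_date = as.Date("2015-10-01") + c(0, 5)
  )
  s <- stay_durations(areas)
  expect_equal(s$mean_days, 3)
  expect_equal(s$sd_days, sqrt(2), tolerance = 1e-12)

  one <- stay_durations(areas[1, ])
  expect_equal(one$sd_days, 0)
  expect_false(one$sd_defined)

  same <- stay_durations(tibble::tibble(
    bird_id = "A", duration_days = c(3L, 3L, 3L),
    start_date = as.Date("2015-10-01") + c(0, 4, 8)
  ))
  expect_equal(same$sd_days, 0)
  expect_true(same$sd_defined)
})

test_that("areas export as a valid GeoJSON feature collection", {
  fx <- two_patch_traj(20000)
  seg <- segment_areas(daily_movements(fx), fx, threshold = 3, proj = TEST_PROJ)
  path <- withr::local_tempfile(fileext = ".geojson")
  areas_to_geojson(seg, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 2)
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  ring <- f1$geometry$coordinates[[1]]
  expect_equal(ring[[1]], ring[[length(ring)]]) # closed ring
  expect_equal(f1$properties$duration_days, 5)
})
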