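test_that("orthogonal polynomial basis matches hand Gram-Schmidt on [-1, 0, 1]", {
  op <- ortho_poly(c(-1, 0, 1), degree = 2)
  expect_equal(op$basis[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(op$basis[, 2], c(1, -2, 1) / sqrt(6), tolerance = 1e-12)
  # transforming the training values reproduces the training columns
  expect_equal(predict(op, c(-1, 0, 1)), op$basis, tolerance = 1e-12)
  expect_error(ortho_poly(c(1, 1, 1)), "distinct")
})

test_that("basis columns are centred, orthonormal, and extend to new data", {
  withr::with_seed(6, x <- runif(50, -0.8, -0.1))
  op <- ortho_poly(x, 2)
  b <- op$basis
  expect_lt(abs(sum(b[, 1])), 1e-10)
  expect_lt(abs(sum(b[, 2])), 1e-10)
  expect_lt(abs(sum(b[, 1] * b[, 2])), 1e-10)
  expect_equal(colSums(b^2), c(1, 1), tolerance = 1e-10, ignore_attr = TRUE)
  # the stored transform is a polynomial in x
  new <- predict(op, c(-0.5, -0.3))
  expect_equal(nrow(new), 2)
})

test_that("design construction emits the paired rows per model", {
  # two consecutive areas of 10 and 8 occupied days
  s <- dplyr::bind_rows(
    manual_samples("A", 1L, 2015L, "presence", seq(-0.5, -0.4, length.out = 10)),
    manual_samples("A", 1L, 2015L, "pre_abandonment_week", seq(-0.48, -0.4, length.out = 7)),
    manual_samples("A", 1L, 2015L, "post_arrival_week", seq(-0.5, -0.45, length.out = 7)),
    manual_samples("A", 1L, 2015L, "post_abandonment", seq(-0.55, -0.5, length.out = 7)),
    manual_samples("A", 2L, 2015L, "presence", seq(-0.45, -0.38, length.out = 8)),
    manual_samples("A", 2L, 2015L, "pre_abandonment_week", seq(-0.44, -0.38, length.out = 7)),
    manual_samples("A", 2L, 2015L, "post_arrival_week", seq(-0.46, -0.4, length.out = 7)),
    manual_samples("A", 2L, 2015L, "post_abandonment", seq(-0.5, -0.45, length.out = 7))
  )
  a <- build_design(s, "a")
  expect_equal(nrow(a), (10 + 8) + (7 + 7))
  expect_equal(sum(a$response == 1), 14)

  b <- build_design(s, "b")
  expect_equal(nrow(b), 14) # last week of area 1 (0) + first week of area 2 (1)
  expect_equal(sum(b$response == 0), 7)
  expect_true(all(b$area_id[b$response == 0] == 1))
  expect_true(all(b$area_id[b$response == 1] == 2))

  # a single area has no successor: model b gets nothing
  b1 <- build_design(s[s$area_id == 1, ], "b")
  expect_equal(nrow(b1), 0)

  # areas of different birds or years never pair
  s2 <- s
  s2$bird_id[s2$area_id == 2] <- "B"
  expect_equal(nrow(build_design(s2, "b")), 0)
})

test_that("the glmm recovers known fixed effects when random variances are zero", {
  withr::with_seed(101, {
    n <- 2000
    x <- runif(n, -0.8, -0.1)
    B <- ortho_poly(x, 2)$basis
    eta <- 2 * sqrt(n) * B[, 1] # slope 2 per unit of the n-normalised column
    y <- rbinom(n, 1, plogis(eta))
    obs <- tibble::tibble(
      response = y, ndwi = x,
      bird_id = sample(LETTERS[1:5], n, TRUE),
      area_id = sample(1:4, n, TRUE),
      year = sample(2014:2015, n, TRUE),
      bird_area = paste0("g", sample(1:10, n, TRUE)),
      phase = "synthetic"
    )
  })
  fit <- suppressWarnings(fit_binomial_glmm(obs, fixed = "poly2"))
  # the fitted coefficient is on the orthonormal column: truth 2 * sqrt(n)
  expect_lt(abs(fit$terms$estimate[2] / sqrt(2000) - 2), 0.3)
  expect_true(all(fit$ranef_var$variance < 0.05))
  expect_equal(fit$r2[["conditional"]], fit$r2[["marginal"]], tolerance = 0.02)
})

test_that("ndwi terms are non-significant when the response is independent", {
  withr::with_seed(202, {
    seeds <- sample.int(1e6, 50)
  })
  hits <- vapply(seeds, function(s) {
    withr::with_seed(s, {
      n <- 2000
      x <- runif(n, -0.8, -0.1)
      obs <- tibble::tibble(
        response = rbinom(n, 1, 0.5), ndwi = x,
        bird_id = "A", area_id = 1L,
        year = sample(2014:2015, n, TRUE),
        bird_area = paste0("g", sample(1:10, n, TRUE)),
        phase = "synthetic"
      )
    })
    fit <- suppressWarnings(fit_binomial_glmm(obs, fixed = "poly2"))
    abs(fit$terms$z[fit$terms$term == "ndwi_poly1"]) < 1.96
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("complete separation raises a diagnostic error", {
  x <- seq(-0.8, -0.1, length.out = 40)
  obs <- tibble::tibble(
    response = as.numeric(x > -0.45), ndwi = x,
    bird_id = "A", area_id = 1L, year = rep(2014:2015, 20),
    bird_area = rep(c("g1", "g2"), 20), phase = "synthetic"
  )
  expect_error(fit_binomial_glmm(obs, fixed = "linear"), "separation")
})

test_that("single-level random factors are dropped with a warning", {
  withr::with_seed(9, {
    n <- 200
    obs <- tibble::tibble(
      response = rbinom(n, 1, 0.5), ndwi = runif(n, -0.8, -0.1),
      bird_id = "A", area_id = 1L, year = 2015L,
      bird_area = paste0("g", sample(1:4, n, TRUE)), phase = "synthetic"
    )
  })
  expect_warning(fit <- fit_binomial_glmm(obs, fixed = "linear"), "single level")
  expect_equal(fit$ranef_var$group, "bird_area")
})

test_that("Nakagawa R2 reproduces the closed form and its identities", {
  r2 <- r2_nakagawa(1, 1)
  expect_equal(r2[["marginal"]], 1 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(r2[["conditional"]], 2 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(round(r2[["marginal"]], 3), 0.189)
  expect_equal(round(r2[["conditional"]], 3), 0.378)

  # no random variance: conditional equals marginal
  r2f <- r2_nakagawa(0.7, 0)
  expect_equal(r2f[["marginal"]], r2f[["conditional"]])
  # no fixed variance: marginal is zero
  expect_equal(r2_nakagawa(0, c(0.3, 0.2))[["marginal"]], 0)
})

test_that("conditional >= marginal and both are invariant to affine NDWI rescaling", {
  withr::with_seed(404, {
    n <- 600
    x <- runif(n, -0.8, -0.1)
    B <- ortho_poly(x, 2)$basis
    grp <- sample(1:8, n, TRUE)
    re <- rnorm(8, 0, 0.8)
    y <- rbinom(n, 1, plogis(0.3 + 10 * B[, 1] + re[grp]))
    obs <- tibble::tibble(
      response = y, ndwi = x, bird_id = "A", area_id = 1L,
      year = sample(2013:2015, n, TRUE),
      bird_area = paste0("g", grp), phase = "synthetic"
    )
  })
  fit <- suppressWarnings(fit_binomial_glmm(obs, fixed = "poly2"))
  expect_gte(fit$r2[["conditional"]], fit$r2[["marginal"]])
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))

  obs2 <- obs
  obs2$ndwi <- 2 + 3 * obs$ndwi # affine rescale; orthogonal basis unchanged
  fit2 <- suppressWarnings(fit_binomial_glmm(obs2, fixed = "poly2"))
  expect_equal(fit$r2, fit2$r2, tolerance = 1e-3)
  expect_equal(fit$terms$z, fit2$terms$z, tolerance = 1e-3)
})

test_that("response curves centre at the intercept and tighten with sample size", {
  make_fit <- function(n, seed) {
    withr::with_seed(seed, {
      x <- runif(n, -0.8, -0.1)
      B <- ortho_poly(x, 2)$basis
      y <- rbinom(n, 1, plogis(-0.4 + 5 * B[, 1]))
      obs <- tibble::tibble(
        response = y, ndwi = x, bird_id = "A", area_id = 1L,
        year = sample(2014:2015, n, TRUE),
        bird_area = paste0("g", sample(1:6, n, TRUE)), phase = "synthetic"
      )
    })
    list(fit = suppressWarnings(fit_binomial_glmm(obs, fixed = "poly2")), x = obs$ndwi)
  }
  big <- make_fit(2000, 11)
  # centring identity of the orthogonal basis: the linear predictor
  # averaged over the training values equals the intercept
  pr <- predict_response_curve(big$fit, big$x)
  expect_equal(mean(qlogis(pr$fit)), big$fit$terms$estimate[1], tolerance = 1e-8)

  small <- make_fit(200, 12)
  grid <- seq(-0.7, -0.2, length.out = 9)
  w_small <- predict_response_curve(small$fit, grid)
  w_big <- predict_response_curve(big$fit, grid)
  expect_lt(mean(w_big$upr - w_big$lwr), mean(w_small$upr - w_small$lwr))

  expect_warning(predict_response_curve(big$fit, c(-2, 0.5)), "extrapolat")
})

test_that("a monotone linear model predicts monotonically in ndwi", {
  withr::with_seed(31, {
    n <- 500
    x <- runif(n, -0.8, -0.1)
    y <- rbinom(n, 1, plogis(1 + 4 * x))
    obs <- tibble::tibble(
      response = y, ndwi = x, bird_id = "A", area_id = 1L,
      year = sample(2014:2015, n, TRUE),
      bird_area = paste0("g", sample(1:6, n, TRUE)), phase = "synthetic"
    )
  })
  fit <- suppressWarnings(fit_binomial_glmm(obs, fixed = "linear"))
  grid <- seq(min(obs$ndwi), max(obs$ndwi), length.out = 20)
  pr <- predict_response_curve(fit, grid)
  expect_true(all(diff(pr$fit) > 0) || all(diff(pr$fit) < 0))
})
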