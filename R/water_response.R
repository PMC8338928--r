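# Paired binary designs and the two binomial mixed models:
#   model a - presence (0) vs post-abandonment (1): does the occupied
#             ground dry or wet after the bird leaves?
#   model b - last week before abandonment (0) vs first week after arrival
#             in the next area (1): do birds pick areas with the same
#             surface water they just left?
# Fixed effect: daily mean NDWI, as an orthogonal second-degree polynomial
# (model a; abandonment can follow both drying and wetting) or linear
# (model b). Random intercepts: year, and area nested within bird.

#' Build the paired observation table for one model
#'
#' Model `"a"` emits, per abandoned area, the presence rows (response 0)
#' and the post-abandonment rows (response 1). Model `"b"` pairs each area
#' with its successor in the same bird and year: pre-abandonment-week rows
#' of the earlier area (0) with post-arrival-week rows of the next area
#' (1); areas without a successor contribute nothing. Areas missing one
#' side of their pair are dropped and counted in the `dropped_areas`
#' attribute.
#'
#' @param samples Phase samples from [phase_samples_all()].
#' @param model `"a"` or `"b"`.
#' @return A tibble: `response` (0/1), `ndwi`, `bird_id`, `area_id`,
#'   `year`, `bird_area` (nested grouping key `bird:year:area`), `phase`.
#' @export
build_design <- function(samples, model = c("a", "b")) {
  model <- match.arg(model)
  s <- samples
  s$bird_area <- paste(s$bird_id, s$year, s$area_id, sep = ":")
  dropped <- character()
  if (model == "a") {
    pres <- s[s$phase == "presence", , drop = FALSE]
    post <- s[s$phase == "post_abandonment", , drop = FALSE]
    keep <- intersect(unique(pres$bird_area), unique(post$bird_area))
    dropped <- setdiff(unique(s$bird_area), keep)
    pres <- pres[pres$bird_area %in% keep, , drop = FALSE]
    post <- post[post$bird_area %in% keep, , drop = FALSE]
    out <- dplyr::bind_rows(
      dplyr::mutate(pres, response = 0),
      dplyr::mutate(post, response = 1)
    )
  } else {
    pre <- s[s$phase == "pre_abandonment_week", , drop = FALSE]
    arr <- s[s$phase == "post_arrival_week", , drop = FALSE]
    pieces <- list()
    keys <- unique(s[, c("bird_id", "year")])
    for (i in seq_len(nrow(keys))) {
      ids <- sort(unique(s$area_id[s$bird_id == keys$bird_id[i] & s$year == keys$year[i]]))
      for (a in ids) {
        if (!((a + 1) %in% ids)) next # no successor: area contributes nothing
        p0 <- pre[pre$bird_id == keys$bird_id[i] & pre$year == keys$year[i] &
          pre$area_id == a, , drop = FALSE]
        p1 <- arr[arr$bird_id == keys$bird_id[i] & arr$year == keys$year[i] &
          arr$area_id == a + 1, , drop = FALSE]
        if (nrow(p0) == 0 || nrow(p1) == 0) {
          dropped <- c(dropped, paste(keys$bird_id[i], keys$year[i], a, sep = ":"))
          next
        }
        pieces[[length(pieces) + 1]] <- dplyr::bind_rows(
          dplyr::mutate(p0, response = 0),
          dplyr::mutate(p1, response = 1)
        )
      }
    }
    out <- dplyr::bind_rows(pieces)
  }
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      response = numeric(), ndwi = numeric(), bird_id = character(),
      area_id = integer(), year = integer(), bird_area = character(),
      phase = character()
    )
  } else {
    out <- tibble::tibble(
      response = out$response, ndwi = out$daily_mean_ndwi,
      bird_id = out$bird_id, area_id = out$area_id, year = out$year,
      bird_area = out$bird_area, phase = out$phase
    )
  }
  attr(out, "dropped_areas") <- unique(dropped)
  out
}

#' Orthogonal polynomial basis with a reusable transform
#'
#' Degree-2 orthonormal polynomial columns (Gram-Schmidt on `[1, x, x^2]`
#' with the constant column removed, as produced by [stats::poly()]); the
#' centring/scaling constants are stored so new values can be projected
#' onto the training basis.
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @param degree Polynomial degree (default 2).
#' @return An object of class `ortho_poly`: list with `basis` (matrix),
#'   `coefs`, `degree`, `range`.
#' @export
ortho_poly <- function(x, degree = 2) {
  if (length(unique(x)) < degree + 1) {
    stop("need at least ", degree + 1, " distinct values for a degree-", degree, " basis")
  }
  p <- stats::poly(x, degree = degree)
  structure(
    list(
      basis = unclass(p)[, , drop = FALSE],
      coefs = attr(p, "coefs"),
      degree = degree,
      range = range(x)
    ),
    class = "ortho_poly"
  )
}

#' @export
predict.ortho_poly <- function(object, newdata, ...) {
  unclass(stats::poly(newdata, degree = object$degree, coefs = object$coefs))[, , drop = FALSE]
}

#' Fit a paired binomial mixed model
#'
#' Logistic mixed model by Laplace-approximated maximum likelihood
#' ([lme4::glmer()], bobyqa optimiser), with random intercepts for year
#' and for area nested within bird (`bird:year:area` key, so equally
#' numbered areas of different birds are never pooled). Fixed effects are
#' an orthogonal degree-2 polynomial of NDWI (`fixed = "poly2"`) or raw
#' NDWI (`fixed = "linear"`). Wald z-tests per term; complete separation
#' raises an error rather than returning a silently divergent fit; a
#' grouping factor with a single level is dropped with a warning.
#'
#' @param obs Output of [build_design()].
#' @param fixed `"poly2"` or `"linear"`.
#' @return An object of class `water_glmm`: list with `terms` (tibble:
#'   term, estimate, se, z, p), `ranef_var` (tibble: group, variance),
#'   `r2` (marginal, conditional), `converged`, `optimizer`, `nobs`,
#'   `model` (the `glmerMod`/`glm`), `poly` (the basis, for `"poly2"`),
#'   `ndwi_range`, `fixed`.
#' @export
fit_binomial_glmm <- function(obs, fixed = c("poly2", "linear")) {
  fixed <- match.arg(fixed)
  stopifnot(nrow(obs) > 0)
  if (length(unique(obs$response)) < 2) {
    stop("both response classes must be present")
  }
  dat <- data.frame(
    response = obs$response,
    year = factor(obs$year),
    bird_area = factor(obs$bird_area)
  )
  op <- NULL
  if (fixed == "poly2") {
    op <- ortho_poly(obs$ndwi, 2)
    dat$ndwi_poly1 <- op$basis[, 1]
    dat$ndwi_poly2 <- op$basis[, 2]
    fix_terms <- c("ndwi_poly1", "ndwi_poly2")
  } else {
    dat$ndwi <- obs$ndwi
    fix_terms <- "ndwi"
  }

  check_separation(dat, fix_terms)

  re_terms <- character()
  for (g in c("year", "bird_area")) {
    if (nlevels(dat[[g]]) >= 2) {
      re_terms <- c(re_terms, sprintf("(1 | %s)", g))
    } else {
      warning("random term '", g, "' has a single level and was dropped")
    }
  }
  rhs <- paste(c(fix_terms, re_terms), collapse = " + ")
  form <- stats::as.formula(paste("response ~", rhs))

  if (length(re_terms) == 0) {
    fit <- stats::glm(form, data = dat, family = stats::binomial())
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    vr <- tibble::tibble(group = character(), variance = numeric())
    converged <- fit$converged
    optimizer <- "glm-irls"
  } else {
    fit <- lme4::glmer(form, data = dat, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa")
    )
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    vr <- tibble::tibble(
      group = names(vc),
      variance = vapply(vc, function(m) m[1, 1], 0)
    )
    converged <- length(fit@optinfo$conv$lme4) == 0
    optimizer <- "bobyqa (lme4::glmer, Laplace)"
  }
  z <- beta / se
  terms <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(2 * stats::pnorm(-abs(z)))
  )
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(fix_terms, collapse = "+"))), dat)
  out <- structure(
    list(
      terms = terms,
      ranef_var = vr,
      converged = converged,
      optimizer = optimizer,
      nobs = nrow(dat),
      model = fit,
      poly = op,
      fixed = fixed,
      ndwi_range = range(obs$ndwi),
      X = X
    ),
    class = "water_glmm"
  )
  out$r2 <- r2_nakagawa(out)
  out
}

# Complete separation makes the binomial likelihood unbounded; detect it
# with a cheap fixed-effects glm whose fitted probabilities all collapse
# onto the responses.
check_separation <- function(dat, fix_terms) {
  form <- stats::as.formula(paste("response ~", paste(fix_terms, collapse = "+")))
  g <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  if (all(abs(stats::fitted(g) - dat$response) < 1e-6)) {
    stop("complete separation: NDWI perfectly predicts the response; the MLE diverges")
  }
  invisible(NULL)
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a logit-link binomial mixed model:
#' `marginal = var_f / (var_f + sum(var_r) + pi^2 / 3)` and
#' `conditional = (var_f + sum(var_r)) / (var_f + sum(var_r) + pi^2 / 3)`,
#' where `var_f` is the variance of the fixed-effect linear predictor over
#' the data, `var_r` the random-intercept variances, and `pi^2 / 3` the
#' logit distribution-specific variance.
#'
#' @param fit A `water_glmm` object, or the fixed-predictor variance
#'   (scalar) when calling the closed form directly.
#' @param var_random Random-effect variances (vector), for the closed
#'   form; ignored when `fit` is a `water_glmm`.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit, var_random = NULL) {
  if (inherits(fit, "water_glmm")) {
    beta <- fit$terms$estimate
    var_f <- stats::var(as.vector(fit$X %*% beta))
    var_r <- fit$ranef_var$variance
  } else {
    stopifnot(is.numeric(fit), length(fit) == 1, fit >= 0)
    var_f <- fit
    var_r <- if (is.null(var_random)) 0 else var_random
  }
  denom <- var_f + sum(var_r) + pi^2 / 3
  c(marginal = var_f / denom, conditional = (var_f + sum(var_r)) / denom)
}

#' Population-level response curve with 95% confidence band
#'
#' Inverse-logit predictions over an NDWI grid with random effects at
#' zero; the confidence band is the Wald (delta-method) interval on the
#' link scale, back-transformed. Grid values outside the observed NDWI
#' range raise an extrapolation warning.
#'
#' @param fit A `water_glmm`.
#' @param ndwi_grid Numeric vector of NDWI values.
#' @return A tibble: `ndwi`, `fit`, `lwr`, `upr` (probabilities).
#' @export
predict_response_curve <- function(fit, ndwi_grid) {
  stopifnot(inherits(fit, "water_glmm"))
  if (any(ndwi_grid < fit$ndwi_range[1] | ndwi_grid > fit$ndwi_range[2])) {
    warning("ndwi_grid extends beyond the observed NDWI range: extrapolating")
  }
  if (fit$fixed == "poly2") {
    B <- predict(fit$poly, ndwi_grid)
    X <- cbind(1, B)
  } else {
    X <- cbind(1, ndwi_grid)
  }
  beta <- fit$terms$estimate
  V <- as.matrix(stats::vcov(fit$model))
  eta <- as.vector(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  tibble::tibble(
    ndwi = ndwi_grid,
    fit = stats::plogis(eta),
    lwr = stats::plogis(eta - 1.96 * se),
    upr = stats::plogis(eta + 1.96 * se)
  )
}

#' Did a fitted abandonment model recover the direction of an NDWI shift?
#'
#' The shift direction is recovered when (i) the abandonment-phase rows
#' are shifted relative to the presence rows in the expected direction,
#' and (ii) the fitted response curve assigns a higher abandonment
#' probability at the abandonment-phase mean NDWI than at the presence
#' mean — i.e. the model, not just the raw means, discriminates the two
#' phases in that direction.
#'
#' @param fit A `water_glmm` fitted on `obs`.
#' @param obs The design the model was fitted on ([build_design()]).
#' @param expected_sign `-1` for drying, `+1` for wetting.
#' @return Logical.
#' @export
shift_sign_recovered <- function(fit, obs, expected_sign) {
  stopifnot(expected_sign %in% c(-1, 1))
  m0 <- mean(obs$ndwi[obs$response == 0])
  m1 <- mean(obs$ndwi[obs$response == 1])
  if (sign(m1 - m0) != expected_sign) {
    return(FALSE)
  }
  pr <- suppressWarnings(predict_response_curve(fit, c(m0, m1)))
  pr$fit[2] > pr$fit[1]
}

#' @export
print.water_glmm <- function(x, ...) {
  cat(sprintf(
    "<binomial GLMM (%s NDWI): %d obs, %s>\n",
    if (x$fixed == "poly2") "poly-2" else "linear", x$nobs,
    if (x$converged) "converged" else "NOT converged"
  ))
  tt <- x$terms
  for (i in seq_len(nrow(tt))) {
    cat(sprintf(
      "  %-12s % .3f (%.3f)  z = % .2f  p = %.3g\n",
      tt$term[i], tt$estimate[i], tt$se[i], tt$z[i], tt$p[i]
    ))
  }
  if (nrow(x$ranef_var) > 0) {
    cat("  random-intercept variances:",
      paste(sprintf("%s %.4f", x$ranef_var$group, x$ranef_var$variance), collapse = ", "), "\n")
  }
  cat(sprintf(
    "  marginal R2 %.3f / conditional R2 %.3f\n",
    x$r2[["marginal"]], x$r2[["conditional"]]
  ))
  invisible(x)
}

#' Export a fitted model as a JSON report
#'
#' Mirrors the usual reporting table: estimate (SE), z, p per fixed term,
#' random-intercept variances, marginal/conditional R-squared, optimizer
#' and convergence status.
#'
#' @param fit A `water_glmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      fixed = fit$fixed,
      nobs = fit$nobs,
      converged = fit$converged,
      optimizer = fit$optimizer,
      terms = fit$terms,
      random_variances = fit$ranef_var,
      marginal_r2 = fit$r2[["marginal"]],
      conditional_r2 = fit$r2[["conditional"]]
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
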