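# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: distances use the spherical law of cosines
# or an explicit haversine loop, kernel sums a double loop, and polygon
# overlap a classical vertex-containment / edge-intersection test.

EARTH_R_KM <- 6371.0088

# Spherical law of cosines (different formula from the haversine the
# implementation uses; agrees to ~1e-9 at these scales).
slc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  EARTH_R_KM * acos(pmin(1, pmax(-1, d)))
}

# Explicit scalar haversine, for the pairwise-max oracle.
hav_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * EARTH_R_KM * asin(sqrt(a))
}

max_pairwise_oracle <- function(lon, lat) {
  n <- length(lon)
  best <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      best <- max(best, hav_km(lon[i], lat[i], lon[j], lat[j]))
    }
  }
  best
}

# Brute-force bivariate normal kernel sum at one evaluation point.
kde_oracle <- function(x, y, h, px, py) {
  s <- 0
  for (i in seq_along(x)) {
    s <- s + stats::dnorm(px - x[i], sd = h) * stats::dnorm(py - y[i], sd = h)
  }
  s / length(x)
}

# --- independent convex-polygon overlap test -------------------------------

point_in_convex <- function(px, py, verts) {
  n <- nrow(verts)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (verts[j, 1] - verts[i, 1]) * (py - verts[i, 2]) -
      (verts[j, 2] - verts[i, 2]) * (px - verts[i, 1])
    if (abs(cr) < 1e-9) next
    if (sgn == 0) sgn <- sign(cr) else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1)
  d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3)
  d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    abs(d(a, b, c)) < 1e-9 &&
      min(a[1], b[1]) - 1e-9 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-9 &&
      min(a[2], b[2]) - 1e-9 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-9
  }
  on_seg(p3, p4, p1) || on_seg(p3, p4, p2) || on_seg(p1, p2, p3) || on_seg(p1, p2, p4)
}

overlap_oracle <- function(va, vb) {
  for (i in seq_len(nrow(va))) {
    if (point_in_convex(va[i, 1], va[i, 2], vb)) {
      return(TRUE)
    }
  }
  for (i in seq_len(nrow(vb))) {
    if (point_in_convex(vb[i, 1], vb[i, 2], va)) {
      return(TRUE)
    }
  }
  na <- nrow(va)
  nb <- nrow(vb)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1 else i + 1
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1 else j + 1
      if (segments_intersect(va[i, ], va[i2, ], vb[j, ], vb[j2, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# --- brute-force residence-area segmentation -------------------------------

# Enumerates staying runs and applies the pairwise merge rule with the
# independent overlap oracle; MCP peeling is re-derived from its
# definition (distance sort from the mean centroid, then chull).
mcp_oracle <- function(x, y, retain = 0.95) {
  n <- length(x)
  k <- floor((1 - retain) * n)
  if (k > 0) {
    d2 <- (x - mean(x))^2 + (y - mean(y))^2
    drop <- order(-d2, seq_along(d2))[seq_len(k)]
    x <- x[-drop]
    y <- y[-drop]
  }
  pts <- unique(cbind(x, y))
  pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
}

segment_oracle <- function(daily_one_bird, fx_one_bird, thr_km, retain = 0.95) {
  dd <- daily_one_bird[order(daily_one_bird$date), ]
  stay <- dd$date[dd$effective_distance_km <= thr_km]
  if (length(stay) == 0) {
    return(list())
  }
  grp <- cumsum(c(1, as.integer(diff(stay)) != 1))
  runs <- unname(split(stay, grp))
  runs <- runs[lengths(runs) >= 2]
  segs <- lapply(runs, function(r) {
    rows <- fx_one_bird[fx_one_bird$date %in% r, ]
    list(days = r, x = rows$x, y = rows$y)
  })
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(segs)) {
      va <- mcp_oracle(segs[[i]]$x, segs[[i]]$y, retain)
      vb <- mcp_oracle(segs[[i + 1]]$x, segs[[i + 1]]$y, retain)
      if (overlap_oracle(va, vb)) {
        segs[[i]] <- list(
          days = sort(unique(c(segs[[i]]$days, segs[[i + 1]]$days))),
          x = c(segs[[i]]$x, segs[[i + 1]]$x),
          y = c(segs[[i]]$y, segs[[i + 1]]$y)
        )
        segs[[i + 1]] <- NULL
        merged <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged) break
  }
  segs
}
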