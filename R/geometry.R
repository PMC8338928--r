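# Planar convex-polygon primitives: percent minimum convex polygons, signed
# areas, and an overlap test. All coordinates are metres in a local planar
# projection (see local_projection()).

#' Percent minimum convex polygon
#'
#' Removes the `floor((1 - retain) * n)` points farthest from the arithmetic
#' mean centroid of all points, then returns the convex hull of the
#' remainder. With the default `retain = 0.95` this is the 95% MCP commonly
#' used for residence areas.
#'
#' Fewer than three distinct retained points, or a collinear point set,
#' yield a *degenerate* polygon (flagged); downstream overlap tests buffer
#' degenerate geometry by one grid cell.
#'
#' @param x,y Planar coordinates in metres.
#' @param retain Fraction of points to retain (default 0.95).
#' @return An object of class `mcp`: list with `vertices` (two-column
#'   matrix, counter-clockwise), `degenerate` (logical), `area_m2`,
#'   `n_used`, `n_peeled`.
#' @export
mcp_polygon <- function(x, y, retain = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 1, retain > 0, retain <= 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  n_peel <- floor((1 - retain) * n)
  if (n_peel > 0) {
    cx <- mean(x)
    cy <- mean(y)
    d2 <- (x - cx)^2 + (y - cy)^2
    # farthest first; ties resolved by original index order for determinism
    drop_idx <- order(-d2, seq_along(d2))[seq_len(n_peel)]
    x <- x[-drop_idx]
    y <- y[-drop_idx]
  }
  pts <- unique(cbind(x = x, y = y))
  if (nrow(pts) < 3) {
    return(new_mcp(pts, degenerate = TRUE, n_used = length(x), n_peeled = n_peel))
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  verts <- pts[hull, , drop = FALSE]
  a <- polygon_signed_area(verts)
  if (abs(a) < .Machine$double.eps * max(1, max(abs(pts)))^2) {
    # collinear: hull has no 2-D extent
    return(new_mcp(verts, degenerate = TRUE, n_used = length(x), n_peeled = n_peel))
  }
  if (a < 0) verts <- verts[rev(seq_len(nrow(verts))), , drop = FALSE]
  new_mcp(verts, degenerate = FALSE, n_used = length(x), n_peeled = n_peel)
}

new_mcp <- function(vertices, degenerate, n_used, n_peeled) {
  structure(
    list(
      vertices = vertices,
      degenerate = degenerate,
      area_m2 = if (degenerate) 0 else abs(polygon_signed_area(vertices)),
      n_used = n_used,
      n_peeled = n_peeled
    ),
    class = "mcp"
  )
}

#' @export
print.mcp <- function(x, ...) {
  cat(sprintf(
    "<mcp: %d vertices, %.3f km2%s (%d points used, %d peeled)>\n",
    nrow(x$vertices), x$area_m2 / 1e6,
    if (x$degenerate) ", degenerate" else "", x$n_used, x$n_peeled
  ))
  invisible(x)
}

# Shoelace formula; positive for counter-clockwise vertex order.
polygon_signed_area <- function(verts) {
  n <- nrow(verts)
  if (n < 3) {
    return(0)
  }
  xs <- verts[, 1]
  ys <- verts[, 2]
  j <- c(n, seq_len(n - 1))
  sum(xs[j] * ys - xs * ys[j]) / 2
}

# Minkowski sum of a point set with an L-infinity ball of radius b:
# the convex hull of every vertex offset to the four corners.
inflate_vertices <- function(verts, b) {
  g <- expand.grid(seq_len(nrow(verts)), 1:2, 1:2)
  pts <- cbind(
    verts[g[, 1], 1] + c(-b, b)[g[, 2]],
    verts[g[, 1], 2] + c(-b, b)[g[, 3]]
  )
  pts <- unique(pts)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  pts[hull, , drop = FALSE]
}

#' Do two convex polygons overlap?
#'
#' Separating-axis test on the edge normals of both polygons. A shared
#' boundary point counts as overlap (separation requires a strict gap), so
#' boundary-touching polygons are deterministically "same area" in the
#' segmentation merge rule. Degenerate polygons (points, segments) are
#' buffered by `buffer_m` before testing.
#'
#' @param a,b `mcp` objects (see [mcp_polygon()]).
#' @param buffer_m Buffer applied to degenerate geometry, in metres;
#'   conventionally one raster grid cell.
#' @return Logical.
#' @export
mcp_overlap <- function(a, b, buffer_m = 500) {
  stopifnot(inherits(a, "mcp"), inherits(b, "mcp"))
  va <- a$vertices
  vb <- b$vertices
  if (a$degenerate) va <- inflate_vertices(va, buffer_m)
  if (b$degenerate) vb <- inflate_vertices(vb, buffer_m)
  !convex_separated(va, vb)
}

# TRUE iff some edge-normal axis strictly separates the two convex hulls.
convex_separated <- function(va, vb) {
  axes <- rbind(edge_normals(va), edge_normals(vb))
  for (i in seq_len(nrow(axes))) {
    ax <- axes[i, ]
    pa <- va %*% ax
    pb <- vb %*% ax
    if (max(pa) < min(pb) || max(pb) < min(pa)) {
      return(TRUE)
    }
  }
  FALSE
}

edge_normals <- function(verts) {
  n <- nrow(verts)
  if (n < 2) {
    # single point: no edges; any axis works, supply coordinate axes
    return(rbind(c(1, 0), c(0, 1)))
  }
  nxt <- c(seq_len(n)[-1], 1)
  ex <- verts[nxt, 1] - verts[, 1]
  ey <- verts[nxt, 2] - verts[, 2]
  keep <- (ex != 0 | ey != 0)
  normals <- cbind(-ey, ex)[keep, , drop = FALSE]
  if (n == 2) normals <- rbind(normals, cbind(ex, ey)[keep, , drop = FALSE])
  normals
}
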