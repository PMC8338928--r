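#' Local equirectangular projection
#'
#' Builds a planar projection about a reference point: metres east/north of
#' `(lon0, lat0)`, with longitudes scaled by `cos(lat0)`. Convex hulls,
#' polygon intersections and kernel grids are planar operations, and at the
#' scale of a residence area or a seasonal home range (tens of km) the
#' distortion of this projection is negligible compared to GPS error.
#'
#' @param lon0,lat0 Reference point in decimal degrees (WGS84).
#' @return An object of class `local_proj`.
#' @seealso [project_xy()], [unproject_xy()]
#' @export
local_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) < 90)
  structure(
    list(
      lon0 = lon0,
      lat0 = lat0,
      # metres per degree on a sphere of mean radius 6371.0088 km
      m_per_deg = pi / 180 * 6371008.8,
      kx = cos(lat0 * pi / 180)
    ),
    class = "local_proj"
  )
}

#' Project lon/lat to local planar metres
#'
#' @param proj A [local_projection()] object.
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return A tibble with columns `x`, `y` (metres).
#' @export
project_xy <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "local_proj"))
  tibble::tibble(
    x = (lon - proj$lon0) * proj$kx * proj$m_per_deg,
    y = (lat - proj$lat0) * proj$m_per_deg
  )
}

#' Inverse of [project_xy()]
#'
#' @inheritParams project_xy
#' @param x,y Planar coordinates in metres.
#' @return A tibble with columns `lon`, `lat` (degrees).
#' @export
unproject_xy <- function(proj, x, y) {
  stopifnot(inherits(proj, "local_proj"))
  tibble::tibble(
    lon = proj$lon0 + x / (proj$kx * proj$m_per_deg),
    lat = proj$lat0 + y / proj$m_per_deg
  )
}

#' @export
print.local_proj <- function(x, ...) {
  cat(sprintf(
    "<local equirectangular projection about lon %.5f, lat %.5f>\n",
    x$lon0, x$lat0
  ))
  invisible(x)
}
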