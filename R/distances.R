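#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km, via
#' [geosphere::distHaversine()]. Vectorised over paired points.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km; `0` for identical points.
#' @examples
#' great_circle_km(30, -12, 30, -11) # one degree of latitude, ~111.2 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(
    all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE),
    all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE)
  )
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0088)
}

# Maximum pairwise great-circle distance among a set of points (km).
# O(n^2) pairs, evaluated in one vectorised haversine call; daily fix
# counts are <= 13 so at most 78 pairs.
max_pairwise_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) {
    return(0)
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  max(great_circle_km(lon[idx[, 1]], lat[idx[, 1]], lon[idx[, 2]], lat[idx[, 2]]))
}
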