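#' Great-circle distance between points, in kilometres
#'
#' The Haversine formula on a sphere of mean Earth radius 6371.0088 km.
#' Vectorised over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pairwise great-circle distance matrix between stands
#'
#' @param stands Stand table with `stand_id`, `latitude`, `longitude`.
#' @return A symmetric stands x stands matrix of distances in km with
#'   attribute `kind = "geographic_km"`.
#' @export
geo_distance <- function(stands) {
  n <- nrow(stands)
  m <- matrix(0, n, n, dimnames = list(stands$stand_id, stands$stand_id))
  for (i in seq_len(n - 1)) {
    j <- seq(i + 1, n)
    d <- haversine_km(stands$latitude[i], stands$longitude[i],
                      stands$latitude[j], stands$longitude[j])
    m[i, j] <- m[j, i] <- d
  }
  attr(m, "kind") <- "geographic_km"
  m
}
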