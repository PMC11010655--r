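#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km. Vectorized over all
#' arguments (recycled).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Radius ladder around a target site
#'
#' Defines the centre and the ladder of search radii used to subset a modern
#' pollen database around a fossil site (default 800-1,400 km at 200-km
#' steps, the standard search range for regional pollen-climate transfer
#' functions).
#'
#' @param center_lon,center_lat centre coordinates in decimal degrees.
#' @param radii_km strictly increasing positive radii in km.
#' @return list of class `radius_spec`.
#' @export
radius_spec <- function(center_lon, center_lat,
                        radii_km = c(800, 1000, 1200, 1400)) {
  if (abs(center_lat) > 90 || abs(center_lon) > 180)
    stop("centre coordinates out of range")
  if (any(radii_km <= 0) || any(diff(radii_km) <= 0))
    stop("radii_km must be positive and strictly increasing")
  structure(list(center_lon = center_lon, center_lat = center_lat,
                 radii_km = radii_km), class = "radius_spec")
}

#' Subset a modern dataset to samples within a radius of the centre
#'
#' Keeps all and only samples whose great-circle distance to the centre is
#' <= `r` km (boundary inclusive); sample ordering is preserved and the
#' retained count is reported via `message()`.
#'
#' @param ds a [modern_dataset()].
#' @param spec a [radius_spec()].
#' @param r one of `spec$radii_km`.
#' @param quiet suppress the count message.
#' @return the subset `modern_dataset`.
#' @export
subset_by_radius <- function(ds, spec, r, quiet = FALSE) {
  stopifnot(inherits(ds, "modern_dataset"), inherits(spec, "radius_spec"))
  if (!r %in% spec$radii_km)
    stop("r must be one of the radii in the radius_spec")
  d <- great_circle_km(spec$center_lon, spec$center_lat,
                       ds$meta$lon, ds$meta$lat)
  keep <- which(d <= r)
  if (!length(keep))
    stop("no samples within ", r,
         " km of the centre; try a larger radius")
  if (!quiet)
    message("radius ", r, " km: retained ", length(keep), " of ",
            nrow(ds$meta), " samples")
  ds_subset(ds, keep)
}
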