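# local planar approximation: degrees -> meters on an equirectangular
# projection about the reference latitude; adequate at metropolitan scale
planar_dist_m <- function(lon1, lat1, lon2, lat2) {
  m_per_deg <- 111320
  lat0 <- (lat1 + lat2) / 2
  dx <- (lon1 - lon2) * cos(lat0 * pi / 180) * m_per_deg
  dy <- (lat1 - lat2) * m_per_deg
  sqrt(dx * dx + dy * dy)
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates station values to a target location as a convex combination
#' `sum(w_i v_i)` with weights proportional to `distance^(-power)` and
#' summing to 1. The estimate therefore always lies within the range of the
#' contributing station values, and as `power` grows it approaches the
#' nearest station's value. A target within `eps` (1 m by default) of a
#' station returns that station's value exactly.
#'
#' @param stations data frame (or matrix) with columns `lon`, `lat`,
#'   `value`; rows with missing values are dropped.
#' @param target numeric `c(lon, lat)`.
#' @param power positive IDW exponent; 2 is the conventional default for
#'   sparse monitoring networks.
#' @param eps station-coincidence tolerance in meters.
#' @return the interpolated value.
#' @examples
#' st <- data.frame(lon = c(0, 0.1), lat = c(0, 0), value = c(10, 20))
#' idw_interpolate(st, c(0.05, 0), power = 2)  # equidistant: 15
#' @export
idw_interpolate <- function(stations, target, power = 2, eps = 1) {
  if (power <= 0) stop("power must be > 0")
  stations <- as.data.frame(stations)
  ok <- !is.na(stations$value)
  if (!any(ok)) stop("no stations with observed values (no-data)")
  s <- stations[ok, , drop = FALSE]
  d <- planar_dist_m(s$lon, s$lat, target[1], target[2])
  at <- which(d < eps)
  if (length(at) > 0L) return(s$value[at[1L]])
  w <- d^(-power)
  sum(w * s$value) / sum(w)
}

#' Assemble lagged per-patient exposure profiles
#'
#' For each patient and pollutant, interpolates the station values observed
#' on the day `lag` days before the patient's clinical presentation to the
#' patient's coordinates by IDW. A patient with any pollutant-day on which
#' no station reported a value is excluded and listed in the exclusion
#' report (mirroring the loss of patients without an exposure profile);
#' run imputation on the measurements first to avoid exclusions.
#'
#' @param cohort data frame with `id`, `lon`, `lat`, `day`.
#' @param stations data frame with `station_id`, `lon`, `lat`.
#' @param measurements data frame with `station_id`, `day`, `pollutant`,
#'   `value` (NA = missing).
#' @param lag exposure lag in days, >= 0; 2 by default (exposure two days
#'   before presentation).
#' @param power IDW exponent.
#' @param pollutants pollutants to assemble; defaults to all present.
#' @return list with `profiles` (data frame: `id` plus one column per
#'   pollutant) and `exclusions` (data frame: `id`, `pollutant`, `day` of
#'   each failed lookup). `nrow(profiles) + n excluded patients` equals the
#'   cohort size.
#' @export
build_exposure_profiles <- function(cohort, stations, measurements,
                                    lag = 2L, power = 2, pollutants = NULL) {
  if (lag < 0) stop("lag must be >= 0")
  if (is.null(pollutants)) pollutants <- sort(unique(measurements$pollutant))
  st_idx <- match(measurements$station_id, stations$station_id)
  if (any(is.na(st_idx))) stop("measurement references an unknown station")
  n <- nrow(cohort)
  prof <- matrix(NA_real_, n, length(pollutants),
                 dimnames = list(NULL, pollutants))
  excl <- list()
  # index measurements by (pollutant, day) once; patients grouped by lagged
  # day so station lookups and distances are computed per group, not per row
  key <- split(seq_len(nrow(measurements)),
               paste(measurements$pollutant, measurements$day, sep = "."))
  lag_day <- cohort$day - lag
  m_per_deg <- 111320
  for (d in unique(lag_day)) {
    pat <- which(lag_day == d)
    for (pol in pollutants) {
      rows <- key[[paste(pol, d, sep = ".")]]
      vals <- measurements$value[rows]
      ok <- !is.na(vals)
      if (is.null(rows) || !any(ok)) {
        excl[[length(excl) + 1L]] <- data.frame(
          id = cohort$id[pat], pollutant = pol, day = d,
          stringsAsFactors = FALSE)
        next
      }
      si <- st_idx[rows[ok]]
      v <- vals[ok]
      lat0 <- mean(c(stations$lat[si], cohort$lat[pat]))
      dx <- outer(cohort$lon[pat], stations$lon[si], `-`) *
        cos(lat0 * pi / 180) * m_per_deg
      dy <- outer(cohort$lat[pat], stations$lat[si], `-`) * m_per_deg
      dist <- sqrt(dx * dx + dy * dy)
      w <- dist^(-power)
      est <- as.numeric(w %*% v) / rowSums(w)
      # exactness at (near-)coincident stations, 1 m tolerance
      hit <- which(dist < 1, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        first <- !duplicated(hit[, 1L])
        est[hit[first, 1L]] <- v[hit[first, 2L]]
      }
      prof[pat, pol] <- est
    }
  }
  complete <- !apply(is.na(prof), 1L, any)
  profiles <- data.frame(id = cohort$id[complete],
                         prof[complete, , drop = FALSE],
                         stringsAsFactors = FALSE, check.names = FALSE)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), pollutant = character(0), day = integer(0),
               stringsAsFactors = FALSE)
  list(profiles = profiles, exclusions = exclusions)
}
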