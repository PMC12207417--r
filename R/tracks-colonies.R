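## Vessel tracks and predator colony fixtures.

.EARTH_RADIUS_KM <- 6371
.KM_PER_NMI <- 1.852

#' Simulate a vessel track by dead reckoning on a sphere
#'
#' Advances the vessel along each segment at constant speed and initial
#' bearing using great-circle forward geodesy (R = 6371 km), emitting one
#' row per \code{stepS} seconds. Activity status is derived from speed via
#' \code{\link{classifyActivityBySpeed}} (fishing window 0.3-5 kn).
#'
#' @param segments data.frame with columns \code{durationS} (s),
#'   \code{speedKn} (knots, >= 0) and \code{headingDeg} (true bearing).
#' @param startLat,startLon initial position, WGS84 degrees.
#' @param startTime POSIXct of the first row.
#' @param stepS row interval in seconds.
#' @param vesselId identifier stored with the track.
#' @return data.frame (a VesselTrack) with columns \code{vessel_id},
#'   \code{timestamp}, \code{lat}, \code{lon}, \code{speed_kn},
#'   \code{status}.
#' @examples
#' seg <- data.frame(durationS = 3600, speedKn = 3, headingDeg = 0)
#' tr <- simulateVesselTrack(seg, startLat = -60.5, startLon = -45.5)
#' range(tr$speed_kn)
#' @export
simulateVesselTrack <- function(segments, startLat, startLon,
                                startTime = as.POSIXct("2022-01-15 00:00:00",
                                                       tz = "UTC"),
                                stepS = 60, vesselId = "SIM") {
  segments <- as.data.frame(segments)
  stopifnot(all(c("durationS", "speedKn", "headingDeg") %in% names(segments)))
  if (any(segments$speedKn < 0)) stop("speeds must be >= 0")
  lat <- startLat; lon <- startLon; t <- 0
  rows <- list(data.frame(t = 0, lat = lat, lon = lon,
                          speed_kn = segments$speedKn[1]))
  for (i in seq_len(nrow(segments))) {
    sp <- segments$speedKn[i]; br <- segments$headingDeg[i] * pi / 180
    nStep <- max(1L, round(segments$durationS[i] / stepS))
    dt <- segments$durationS[i] / nStep
    for (k in seq_len(nStep)) {
      dKm <- sp * .KM_PER_NMI * dt / 3600
      if (dKm > 0) {
        dR <- dKm / .EARTH_RADIUS_KM
        la1 <- lat * pi / 180; lo1 <- lon * pi / 180
        la2 <- asin(sin(la1) * cos(dR) + cos(la1) * sin(dR) * cos(br))
        lo2 <- lo1 + atan2(sin(br) * sin(dR) * cos(la1),
                           cos(dR) - sin(la1) * sin(la2))
        lat <- la2 * 180 / pi
        lon <- ((lo2 * 180 / pi + 180) %% 360) - 180
      }
      t <- t + dt
      rows[[length(rows) + 1L]] <- data.frame(t = t, lat = lat, lon = lon,
                                              speed_kn = sp)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$t), ]
  track <- data.frame(vessel_id = vesselId,
                      timestamp = startTime + out$t,
                      lat = out$lat, lon = out$lon,
                      speed_kn = out$speed_kn,
                      status = NA_character_,
                      stringsAsFactors = FALSE)
  classifyActivityBySpeed(track)
}

#' Generate a random set of predator colonies
#'
#' @param n number of colonies (>= 0).
#' @param bounds named numeric vector or list with \code{latMin},
#'   \code{latMax}, \code{lonMin}, \code{lonMax}.
#' @param populations optional numeric vector of length \code{n}
#'   (individuals, >= 0); drawn log-uniformly in [1e4, 5e5] if omitted.
#' @param seed integer seed.
#' @param taxon taxon label for all colonies.
#' @return data.frame (a ColonySet) with columns \code{colony_id},
#'   \code{lat}, \code{lon}, \code{population}, \code{taxon}.
#' @examples
#' makeColonySet(3, c(latMin = -61, latMax = -60, lonMin = -46, lonMax = -45),
#'               populations = c(5e5, 3e5, 2e5), seed = 1)
#' @export
makeColonySet <- function(n, bounds, populations = NULL, seed = 1L,
                          taxon = "chinstrap_penguin") {
  stopifnot(.isCount(n))
  if (n == 0)
    return(data.frame(colony_id = character(0), lat = numeric(0),
                      lon = numeric(0), population = numeric(0),
                      taxon = character(0), stringsAsFactors = FALSE))
  b <- as.list(bounds)
  withSeed(seed, {
    lat <- stats::runif(n, b$latMin, b$latMax)
    lon <- stats::runif(n, b$lonMin, b$lonMax)
    if (is.null(populations))
      populations <- round(10 ^ stats::runif(n, 4, log10(5e5)))
  })
  if (length(populations) != n) stop("populations must have length n")
  if (any(populations < 0)) stop("populations must be >= 0")
  data.frame(colony_id = sprintf("colony_%02d", seq_len(n)),
             lat = lat, lon = lon, population = populations,
             taxon = taxon, stringsAsFactors = FALSE)
}
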