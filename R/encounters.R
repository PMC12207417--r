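## Encounter-rate normalization, spatial gridding, colony exposure and
## fleet diagnostics.

#' Great-circle distance (haversine, R = 6371 km)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees; vectors recycle.
#' @return distance(s) in kilometres.
#' @examples
#' haversineKm(-60, -45, -61, -45)  # ~111.19 km per degree of latitude
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  toRad <- pi / 180
  dLat <- (lat2 - lat1) * toRad
  dLon <- (lon2 - lon1) * toRad
  a <- sin(dLat / 2) ^ 2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dLon / 2) ^ 2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Classify vessel activity from speed
#'
#' Fishing is the inclusive speed window [loKn, hiKn] (default 0.3 to 5
#' kn); below it the vessel is considered stationary (in port or
#' offloading), above it steaming. Externally supplied status labels
#' (non-NA entries in \code{status}) take precedence over the speed rule.
#'
#' @param track VesselTrack data.frame with column \code{speed_kn}.
#' @param loKn,hiKn fishing window bounds in knots (inclusive).
#' @return the track with a filled \code{status} column.
#' @export
classifyActivityBySpeed <- function(track, loKn = 0.3, hiKn = 5) {
  if (any(track$speed_kn < 0)) stop("speeds must be >= 0")
  derived <- ifelse(track$speed_kn < loKn, "stationary",
                    ifelse(track$speed_kn <= hiKn, "fishing", "steaming"))
  if (!"status" %in% names(track)) track$status <- NA_character_
  keep <- !is.na(track$status)
  track$status[!keep] <- derived[!keep]
  track
}

## status of the track (step function of start timestamps) at times `when`
.statusAt <- function(track, when) {
  o <- order(track$timestamp)
  tt <- as.numeric(track$timestamp)[o]
  st <- track$status[o]
  idx <- findInterval(as.numeric(when), tt)
  out <- rep(NA_character_, length(when))
  out[idx >= 1] <- st[idx[idx >= 1]]
  out
}

#' Restrict events and observation ledger to fishing periods
#'
#' Events and ledger rows are assigned to activity periods by their start
#' timestamp; anything outside "fishing" is removed from both the
#' numerator (predator minutes) and the denominator (observation hours),
#' so exclusion is consistent.
#'
#' @param events DiveEvent data.frame.
#' @param ledger ObservationLedger data.frame (see
#'   \code{\link{makeObservationLedger}}).
#' @param track VesselTrack with status labels covering the period.
#' @return list with filtered \code{events} and \code{ledger}.
#' @export
filterToFishing <- function(events, ledger, track) {
  if (!"status" %in% names(track) || all(is.na(track$status)))
    track <- classifyActivityBySpeed(track)
  evSt <- if (nrow(events)) .statusAt(track, events$timestamp)
          else character(0)
  ldSt <- if (nrow(ledger)) .statusAt(track, ledger$timestamp)
          else character(0)
  list(events = events[!is.na(evSt) & evSt == "fishing", , drop = FALSE],
       ledger = ledger[!is.na(ldSt) & ldSt == "fishing", , drop = FALSE])
}

#' Build an observation ledger from echogram windows
#'
#' One row per analyzed window: its observation hours (non-padded time
#' columns at 1 s each) and its position interpolated from the vessel
#' track at the window midpoint.
#'
#' @param windows list of \linkS4class{Echogram}.
#' @param track optional VesselTrack for positions.
#' @return ObservationLedger data.frame with columns \code{vessel_id},
#'   \code{timestamp}, \code{observation_hours}, \code{lat}, \code{lon}.
#' @export
makeObservationLedger <- function(windows, track = NULL) {
  rows <- lapply(windows, function(w) {
    validCols <- sum(colSums(!is.na(w@image)) > 0)
    data.frame(vessel_id = w@vesselId, timestamp = w@startTimestamp,
               observation_hours = validCols / 3600,
               lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
  })
  led <- do.call(rbind, rows)
  if (!is.null(track) && nrow(track) >= 2 && nrow(led)) {
    tt <- as.numeric(track$timestamp)
    mid <- as.numeric(led$timestamp) + 300
    ok <- mid >= min(tt) & mid <= max(tt)
    led$lat[ok] <- stats::approx(tt, track$lat, xout = mid[ok])$y
    led$lon[ok] <- stats::approx(tt, track$lon, xout = mid[ok])$y
  }
  led
}

.rateRow <- function(key, minutes, hours, nEvents) {
  rate <- if (hours > 0) minutes / hours else NA_real_
  data.frame(key, predator_minutes = minutes, observation_hours = hours,
             n_events = nEvents, rate_min_per_h = rate,
             log_rate = if (is.na(rate)) NA_real_ else log10(rate + 1),
             stringsAsFactors = FALSE)
}

#' Encounter-rate time series
#'
#' Sums predator minutes (kept events only) and observation hours per time
#' bin and class, and reports rate = minutes / hours together with
#' \code{log10(rate + 1)} (1 is added to allow log-transformation when
#' rates are zero). Bins covered by the ledger span but without
#' observation hours are emitted with a missing (not zero) rate.
#'
#' @param events DiveEvent data.frame.
#' @param ledger ObservationLedger data.frame.
#' @param binSeconds bin width in seconds (default 7 days).
#' @param classes predator classes to report.
#' @return data.frame with one row per (bin, class).
#' @export
rateTimeseries <- function(events, ledger, binSeconds = 7 * 86400,
                           classes = c("whale", "bubble_trail")) {
  if (binSeconds <= 0) stop("binSeconds must be > 0")
  events <- keptEvents(events)
  if (!nrow(ledger))
    return(data.frame(bin_start = as.POSIXct(character(0), tz = "UTC"),
                      object_class = character(0),
                      predator_minutes = numeric(0),
                      observation_hours = numeric(0), n_events = integer(0),
                      rate_min_per_h = numeric(0), log_rate = numeric(0)))
  binOf <- function(t) floor(as.numeric(t) / binSeconds)
  lb <- binOf(ledger$timestamp)
  eb <- if (nrow(events)) binOf(events$timestamp) else integer(0)
  allBins <- seq(min(lb), max(c(lb, eb)))
  out <- list()
  for (cl in classes) {
    evc <- events[events$object_class == cl, , drop = FALSE]
    ebc <- if (nrow(evc)) binOf(evc$timestamp) else integer(0)
    for (b in allBins) {
      hours <- sum(ledger$observation_hours[lb == b])
      mins <- sum(evc$duration_min[ebc == b])
      out[[length(out) + 1L]] <- .rateRow(
        data.frame(bin_start = as.POSIXct(b * binSeconds,
                                          origin = "1970-01-01",
                                          tz = "UTC"),
                   object_class = cl, stringsAsFactors = FALSE),
        mins, hours, sum(ebc == b))
    }
  }
  do.call(rbind, out)
}

#' Spatial grid specification
#'
#' Cells are half-open intervals in longitude/latitude, anchored at
#' integer multiples of the cell size from the origin.
#'
#' @param cellLonDeg,cellLatDeg cell size in degrees (> 0).
#' @param originLon,originLat grid origin.
#' @param region optional region label (the study regions use 0.04 degrees
#'   at South Georgia, 0.03 at the South Orkneys, 0.075 at the Antarctic
#'   Peninsula).
#' @return list of class "GridSpec".
#' @export
gridSpec <- function(cellLonDeg, cellLatDeg = cellLonDeg, originLon = 0,
                     originLat = 0, region = "") {
  if (cellLonDeg <= 0 || cellLatDeg <= 0) stop("cell sizes must be > 0")
  structure(list(cellLonDeg = cellLonDeg, cellLatDeg = cellLatDeg,
                 originLon = originLon, originLat = originLat,
                 region = region), class = "GridSpec")
}

.cellIndex <- function(lon, lat, grid) {
  ix <- floor((lon - grid$originLon) / grid$cellLonDeg)
  iy <- floor((lat - grid$originLat) / grid$cellLatDeg)
  list(ix = ix, iy = iy, id = paste0(ix, "_", iy))
}

#' Encounter rates on a spatial grid
#'
#' Events and observation hours are binned to grid cells by position
#' (half-open cell intervals); every cell with observations is reported,
#' including cells without any events. Positionless events are excluded
#' with a message.
#'
#' @param events DiveEvent data.frame with lat/lon.
#' @param ledger ObservationLedger with lat/lon.
#' @param grid a \code{\link{gridSpec}}.
#' @param classes predator classes to report.
#' @return data.frame with one row per (cell, class), including the cell
#'   bounds.
#' @export
rateGrid <- function(events, ledger, grid,
                     classes = c("whale", "bubble_trail")) {
  stopifnot(inherits(grid, "GridSpec"))
  events <- keptEvents(events)
  noPos <- is.na(events$lat) | is.na(events$lon)
  if (any(noPos)) {
    message(sum(noPos), " event(s) without position excluded from the grid")
    events <- events[!noPos, , drop = FALSE]
  }
  ledger <- ledger[!is.na(ledger$lat) & !is.na(ledger$lon), , drop = FALSE]
  lc <- .cellIndex(ledger$lon, ledger$lat, grid)
  ec <- .cellIndex(events$lon, events$lat, grid)
  cells <- unique(data.frame(id = lc$id, ix = lc$ix, iy = lc$iy,
                             stringsAsFactors = FALSE))
  out <- list()
  for (cl in classes) {
    evc <- events$object_class == cl
    for (i in seq_len(nrow(cells))) {
      id <- cells$id[i]
      hours <- sum(ledger$observation_hours[lc$id == id])
      sel <- evc & ec$id == id
      out[[length(out) + 1L]] <- .rateRow(
        data.frame(cell_id = id, object_class = cl,
                   lon_min = cells$ix[i] * grid$cellLonDeg + grid$originLon,
                   lon_max = (cells$ix[i] + 1) * grid$cellLonDeg +
                     grid$originLon,
                   lat_min = cells$iy[i] * grid$cellLatDeg + grid$originLat,
                   lat_max = (cells$iy[i] + 1) * grid$cellLatDeg +
                     grid$originLat,
                   stringsAsFactors = FALSE),
        sum(events$duration_min[sel]), hours, sum(sel))
    }
  }
  do.call(rbind, out)
}

#' Distance to the nearest colony
#'
#' @param positions data.frame with columns lat, lon.
#' @param colonies ColonySet data.frame.
#' @return data.frame with columns \code{distance_km} and
#'   \code{colony_id}.
#' @export
distanceToNearestColony <- function(positions, colonies) {
  if (!nrow(colonies)) stop("colony set is empty")
  n <- nrow(positions)
  D <- matrix(NA_real_, n, nrow(colonies))
  for (j in seq_len(nrow(colonies)))
    D[, j] <- haversineKm(positions$lat, positions$lon,
                          colonies$lat[j], colonies$lon[j])
  j <- max.col(-D, ties.method = "first")
  data.frame(distance_km = D[cbind(seq_len(n), j)],
             colony_id = colonies$colony_id[j], stringsAsFactors = FALSE)
}

#' Colony buffer-zone exposure report
#'
#' Labels events and observation hours by whether they fall inside the
#' colony buffer (default 30 km, the voluntary restricted-zone radius
#' approximating the maximum penguin foraging range) and before/after the
#' management cutoff date, then reports per-stratum encounter rates and the
#' share of encounters within 15 km of a colony.
#'
#' @param events DiveEvent data.frame with positions and timestamps.
#' @param ledger ObservationLedger with positions.
#' @param colonies ColonySet data.frame.
#' @param bufferKm buffer radius in km (default 30).
#' @param cutoff POSIXct/Date management cutoff (default 2018-07-01, the
#'   introduction of the voluntary restricted zones).
#' @param classes predator classes included (default bubble trails, the
#'   penguin-dominated class).
#' @return list with \code{events} (annotated), \code{strata} (rate per
#'   inside/outside x before/after stratum) and
#'   \code{share_within_15km} (fraction of kept events within 15 km).
#' @export
vrzExposure <- function(events, ledger, colonies, bufferKm = 30,
                        cutoff = as.POSIXct("2018-07-01", tz = "UTC"),
                        classes = "bubble_trail") {
  events <- keptEvents(events)
  events <- events[events$object_class %in% classes &
                     !is.na(events$lat), , drop = FALSE]
  ledger <- ledger[!is.na(ledger$lat), , drop = FALSE]
  cutoff <- as.POSIXct(cutoff, tz = "UTC")
  evD <- distanceToNearestColony(events, colonies)
  events$distance_km <- evD$distance_km
  events$nearest_colony <- evD$colony_id
  events$inside_buffer <- events$distance_km <= bufferKm
  events$period <- ifelse(events$timestamp < cutoff, "before", "after")
  ldD <- distanceToNearestColony(ledger, colonies)
  ledger$inside_buffer <- ldD$distance_km <= bufferKm
  ledger$period <- ifelse(ledger$timestamp < cutoff, "before", "after")
  strata <- expand.grid(inside_buffer = c(TRUE, FALSE),
                        period = c("before", "after"),
                        stringsAsFactors = FALSE)
  strata$predator_minutes <- NA_real_
  strata$observation_hours <- NA_real_
  for (i in seq_len(nrow(strata))) {
    es <- events$inside_buffer == strata$inside_buffer[i] &
      events$period == strata$period[i]
    ls <- ledger$inside_buffer == strata$inside_buffer[i] &
      ledger$period == strata$period[i]
    strata$predator_minutes[i] <- sum(events$duration_min[es])
    strata$observation_hours[i] <- sum(ledger$observation_hours[ls])
  }
  strata$rate_min_per_h <- ifelse(strata$observation_hours > 0,
                                  strata$predator_minutes /
                                    strata$observation_hours, NA_real_)
  list(events = events, strata = strata,
       share_within_15km = if (nrow(events))
         mean(events$distance_km <= 15) else NA_real_)
}

#' Krill-consumption equivalent of a penguin population
#'
#' @param nPenguins breeding penguin count (>= 0).
#' @param kgPerPenguin summer krill demand per penguin in kg (default 100).
#' @return tonnes of krill.
#' @examples
#' penguinConsumptionEquivalent(1e6)  # 100,000 tonnes
#' @export
penguinConsumptionEquivalent <- function(nPenguins, kgPerPenguin = 100) {
  if (any(nPenguins < 0) || any(kgPerPenguin < 0))
    stop("inputs must be >= 0")
  nPenguins * kgPerPenguin / 1000
}

#' Median inter-vessel distance over time
#'
#' Interpolates each vessel track to the bin-centre times and reports the
#' median over vessel pairs of the haversine distances at matched times; a
#' fleet-synchrony diagnostic.
#'
#' @param tracks list of at least two VesselTrack data.frames.
#' @param binSeconds time bin width (default 1 day).
#' @return data.frame with columns \code{bin_start},
#'   \code{median_distance_km}, \code{n_pairs}.
#' @export
medianIntervesselDistance <- function(tracks, binSeconds = 86400) {
  if (length(tracks) < 2)
    stop("need at least 2 vessel tracks")
  spans <- vapply(tracks, function(tr)
    range(as.numeric(tr$timestamp)), numeric(2))
  t0 <- max(spans[1, ]); t1 <- min(spans[2, ])
  if (t1 <= t0) stop("tracks do not overlap in time")
  starts <- seq(floor(t0 / binSeconds) * binSeconds, t1, by = binSeconds)
  out <- list()
  for (s in starts) {
    mid <- min(max(s + binSeconds / 2, t0), t1)
    pos <- lapply(tracks, function(tr) {
      tt <- as.numeric(tr$timestamp)
      c(stats::approx(tt, tr$lat, xout = mid, rule = 2)$y,
        stats::approx(tt, tr$lon, xout = mid, rule = 2)$y)
    })
    d <- c()
    for (i in seq_along(pos)) for (j in seq_len(i - 1))
      d <- c(d, haversineKm(pos[[i]][1], pos[[i]][2],
                            pos[[j]][1], pos[[j]][2]))
    out[[length(out) + 1L]] <- data.frame(
      bin_start = as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
      median_distance_km = stats::median(d), n_pairs = length(d))
  }
  do.call(rbind, out)
}

#' Observation hours by hour of day
#'
#' Diel-coverage diagnostic: 24 bins of observation hours by the (local)
#' hour of the ledger row's start time.
#'
#' @param ledger ObservationLedger data.frame.
#' @param utcOffsetH offset added to UTC to obtain local time (default 0).
#' @return data.frame with columns \code{hour} (0-23) and
#'   \code{observation_hours}; the column sums to the ledger total.
#' @export
coverageByHour <- function(ledger, utcOffsetH = 0) {
  hrs <- rep(0, 24)
  if (nrow(ledger)) {
    h <- (as.integer(format(ledger$timestamp, "%H", tz = "UTC")) +
            utcOffsetH) %% 24
    agg <- tapply(ledger$observation_hours, h, sum)
    hrs[as.integer(names(agg)) + 1L] <- agg
  }
  data.frame(hour = 0:23, observation_hours = hrs)
}
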