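# Shared fixtures: tiny records and scenes built in code.

# Raw record with one depth bin and chosen ping times / Sv values.
oneRowRecord <- function(times, sv) {
  new("RawAcousticRecord", sv = matrix(sv, nrow = 1),
      pingTimes = times, depthBins = 0.25, vesselId = "T",
      startTimestamp = as.POSIXct("2022-01-15 00:00:00", tz = "UTC"),
      positions = NULL)
}

# Record already on the standard 1 s x 0.5 m grid.
regularRecord <- function(nT, nD, fill = -80) {
  new("RawAcousticRecord", sv = matrix(fill, nD, nT),
      pingTimes = seq_len(nT) - 1,
      depthBins = seq(0.25, by = 0.5, length.out = nD),
      vesselId = "T",
      startTimestamp = as.POSIXct("2022-01-15 00:00:00", tz = "UTC"),
      positions = NULL)
}

# A scene windowed into its (single) standardized echogram with truth.
sceneWindow <- function(config) {
  sc <- suppressWarnings(simulateScene(config))
  list(window = windowEchograms(regridSv(sc$record), sc$truth)[[1]],
       scene = sc)
}

# Straight-line fishing track covering [start, start + durationS].
fishingTrack <- function(durationS = 3600, speedKn = 2.5,
                         start = as.POSIXct("2022-01-15 00:00:00",
                                            tz = "UTC")) {
  simulateVesselTrack(
    data.frame(durationS = durationS, speedKn = speedKn, headingDeg = 90),
    startLat = -60.6, startLon = -45.6, startTime = start)
}

# Minimal DiveEvent table for encounter-analysis tests.
makeEvents <- function(times, classes = "bubble_trail", durationS = 60,
                       lat = NA_real_, lon = NA_real_) {
  n <- length(times)
  data.frame(event_id = sprintf("ev%02d", seq_len(n)),
             object_class = rep_len(classes, n),
             taxon_group = rep_len("unclassified", n),
             duration_s = rep_len(durationS, n),
             duration_min = rep_len(durationS, n) / 60,
             acoustic_height_m = rep_len(1, n),
             timestamp = times,
             lat = rep_len(lat, n), lon = rep_len(lon, n),
             window_boundary = rep_len(FALSE, n),
             qc_flag = rep_len("kept", n),
             echogram_id = rep_len("eg", n), stringsAsFactors = FALSE)
}

# Greedy matching of extracted events to planted truth events by class
# and nearest start time; each extracted event is used at most once.
matchPlantedEvents <- function(ev, te, windowStart) {
  used <- rep(FALSE, nrow(ev))
  starts <- as.numeric(ev$timestamp - windowStart, units = "secs")
  out <- data.frame(duration_s = rep(NA_real_, nrow(te)),
                    height_m = NA_real_, dStart = NA_real_)
  for (i in seq_len(nrow(te))) {
    cand <- which(!used & ev$object_class == te$object_class[i])
    if (!length(cand)) next
    # two events may start in the same second at different depths, so
    # match on the full (start, duration, height) signature
    cost <- abs(starts[cand] - te$start_s[i]) +
      abs(ev$duration_s[cand] - te$duration_s[i]) +
      2 * abs(ev$acoustic_height_m[cand] - te$height_m[i])
    j <- cand[which.min(cost)]
    used[j] <- TRUE
    out$duration_s[i] <- ev$duration_s[j]
    out$height_m[i] <- ev$acoustic_height_m[j]
    out$dStart[i] <- abs(starts[j] - te$start_s[i])
  }
  out
}

makeLedger <- function(times, hours = 1/6, lat = NA_real_,
                       lon = NA_real_, vessel = "T") {
  data.frame(vessel_id = vessel, timestamp = times,
             observation_hours = rep_len(hours, length(times)),
             lat = rep_len(lat, length(times)),
             lon = rep_len(lon, length(times)), stringsAsFactors = FALSE)
}
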