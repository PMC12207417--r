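t0 <- as.POSIXct("2022-01-15 00:00:00", tz = "UTC")

test_that("the fishing window is inclusive at both bounds", {
  tr <- data.frame(vessel_id = "V", timestamp = t0 + 0:4 * 60,
                   lat = -60, lon = -45,
                   speed_kn = c(0.2, 0.3, 3, 5, 5.01))
  cl <- classifyActivityBySpeed(tr)
  expect_equal(cl$status,
               c("stationary", "fishing", "fishing", "fishing", "steaming"))
  tr$speed_kn[1] <- -1
  expect_error(classifyActivityBySpeed(tr), ">= 0")
  # externally supplied labels win over the speed rule
  tr2 <- data.frame(timestamp = t0, lat = -60, lon = -45, speed_kn = 3,
                    status = "steaming")
  expect_equal(classifyActivityBySpeed(tr2)$status, "steaming")
})

test_that("fishing filtering removes numerator and denominator together", {
  tr <- data.frame(vessel_id = "V",
                   timestamp = t0 + c(0, 3600),
                   lat = -60, lon = -45, speed_kn = c(3, 8),
                   status = NA_character_)
  led <- makeLedger(t0 + c(0, 600, 3600, 4200), hours = 1/6)
  ev <- makeEvents(t0 + c(100, 700))        # both in the fishing hour
  fl <- filterToFishing(ev, led, tr)
  expect_equal(nrow(fl$events), 2)
  expect_equal(sum(fl$ledger$observation_hours), 2/6)  # hours halved
  rateAll <- sum(ev$duration_min) / sum(led$observation_hours)
  rateF <- sum(fl$events$duration_min) / sum(fl$ledger$observation_hours)
  expect_equal(rateF, 2 * rateAll)
  # an event exactly at the status transition follows its start timestamp
  evEdge <- makeEvents(t0 + 3600)
  expect_equal(nrow(filterToFishing(evEdge, led, tr)$events), 0)
})

test_that("rates are minutes per hour with log10(rate + 1)", {
  led <- makeLedger(t0 + (0:59) * 600, hours = 1/6)   # 10 hours
  ev <- makeEvents(t0 + (0:29) * 60, durationS = 60)  # 30 minutes
  rt <- rateTimeseries(ev, led, binSeconds = 86400)
  bt <- rt[rt$object_class == "bubble_trail", ]
  expect_equal(bt$rate_min_per_h, 3.0)
  expect_equal(bt$log_rate, log10(3 + 1))
  wh <- rt[rt$object_class == "whale", ]
  expect_equal(wh$rate_min_per_h, 0)                  # zero events
  expect_equal(wh$log_rate, 0)                        # log10(0 + 1)
})

test_that("re-binning conserves rates; empty bins are missing not zero", {
  led <- makeLedger(t0 + c(0, 86400 * 2) + 100, hours = c(2, 3))
  ev <- makeEvents(t0 + c(200, 86400 * 2 + 200), durationS = c(300, 60))
  fine <- rateTimeseries(ev, led, binSeconds = 86400)
  bt <- fine[fine$object_class == "bubble_trail", ]
  expect_equal(nrow(bt), 3)                     # covering bin included
  expect_true(is.na(bt$rate_min_per_h[2]))      # no observations -> missing
  coarse <- rateTimeseries(ev, led, binSeconds = 4 * 86400)
  btc <- coarse[coarse$object_class == "bubble_trail", ]
  # conservation across the whole series
  expect_equal(sum(btc$predator_minutes), sum(bt$predator_minutes))
  expect_equal(sum(btc$observation_hours), sum(bt$observation_hours))
  # each coarse bin's rate equals the hours-weighted mean of the fine
  # bins it contains
  fineIn <- floor(as.numeric(bt$bin_start) / (4 * 86400))
  for (i in seq_len(nrow(btc))) {
    sel <- fineIn == floor(as.numeric(btc$bin_start[i]) / (4 * 86400))
    if (!any(sel) || sum(bt$observation_hours[sel]) == 0) next
    wm <- sum(bt$rate_min_per_h[sel] * bt$observation_hours[sel],
              na.rm = TRUE) / sum(bt$observation_hours[sel])
    expect_equal(btc$rate_min_per_h[i], wm, tolerance = 1e-9)
  }
})

test_that("grid cells are half-open and conserve totals", {
  g <- gridSpec(0.03)
  led <- makeLedger(t0 + (0:5) * 600, hours = 1/6,
                    lat = -60.585, lon = c(rep(-45.585, 4),
                                           rep(-45.555, 2)))
  ev <- makeEvents(t0 + c(10, 20, 30), durationS = 60,
                   lat = -60.585, lon = c(-45.585, -45.585, -45.555))
  gr <- rateGrid(ev, led, g)
  bt <- gr[gr$object_class == "bubble_trail", ]
  expect_equal(sum(bt$predator_minutes), sum(ev$duration_min))
  expect_equal(sum(bt$observation_hours), sum(led$observation_hours))
  # 2:1 minutes at 2:1 hours -> equal rates; check the cells individually
  expect_equal(sort(bt$n_events), c(1, 2))
  # boundary event: lon exactly on a cell edge belongs to the upper cell
  evb <- makeEvents(t0 + 10, lat = -60.585, lon = -45.57)
  grb <- rateGrid(evb, led, g)
  cell <- grb[grb$n_events == 1, ]
  expect_equal(unique(cell$lon_min), -45.57)
  # positionless events are excluded with a message
  expect_message(rateGrid(makeEvents(t0 + 10), led, g), "without position")
})

test_that("haversine distances match independent oracles", {
  expect_equal(haversineKm(-60, -45, -61, -45), pi * 6371 / 180,
               tolerance = 1e-6)
  set.seed(10)
  lat1 <- runif(40, -65, -50); lon1 <- runif(40, -50, -40)
  lat2 <- lat1 + runif(40, -2, 2); lon2 <- lon1 + runif(40, -2, 2)
  d <- haversineKm(lat1, lon1, lat2, lon2)
  # spherical law of cosines on the same radius
  toR <- pi / 180
  dlc <- 6371 * acos(pmin(1, sin(lat1 * toR) * sin(lat2 * toR) +
    cos(lat1 * toR) * cos(lat2 * toR) * cos((lon2 - lon1) * toR)))
  expect_true(all(abs(d - dlc) < 1e-3))         # within 1 m
  # cross-check against geosphere's haversine (same Earth radius)
  dg <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                 r = 6371000) / 1000
  expect_equal(d, dg, tolerance = 1e-9)
})

test_that("nearest-colony search equals the brute-force minimum", {
  b <- c(latMin = -61, latMax = -60, lonMin = -46, lonMax = -45)
  cs <- makeColonySet(3, b, seed = 4)
  expect_error(distanceToNearestColony(data.frame(lat = -60, lon = -45),
                                       cs[0, ]), "empty")
  # a position at a colony is at distance zero
  at <- distanceToNearestColony(data.frame(lat = cs$lat[2],
                                           lon = cs$lon[2]), cs)
  expect_equal(at$distance_km, 0)
  expect_equal(at$colony_id, cs$colony_id[2])
  set.seed(2)
  pos <- data.frame(lat = runif(20, -61, -60), lon = runif(20, -46, -45))
  got <- distanceToNearestColony(pos, cs)
  for (i in 1:20) {
    dAll <- haversineKm(pos$lat[i], pos$lon[i], cs$lat, cs$lon)
    expect_equal(got$distance_km[i], min(dAll))
  }
})

test_that("buffer membership and the 15-km share behave as constructed", {
  col <- data.frame(colony_id = "c1", lat = -60.5, lon = -45.5,
                    population = 1e6, taxon = "chinstrap_penguin")
  mkAt <- function(km, when) {
    ev <- makeEvents(when, lat = -60.5 + km / 111.1949, lon = -45.5)
    ev
  }
  led <- makeLedger(t0, hours = 1, lat = -60.5, lon = -45.5)
  before <- as.POSIXct("2017-01-01", tz = "UTC")
  after <- as.POSIXct("2022-01-01", tz = "UTC")
  ev <- rbind(mkAt(29, after), mkAt(31, after), mkAt(10, before))
  ex <- vrzExposure(ev, led, col, bufferKm = 30)
  expect_equal(ex$events$inside_buffer, c(TRUE, FALSE, TRUE))
  expect_equal(ex$events$period, c("after", "after", "before"))
  # all events at 10 km -> the within-15-km share is 100%
  ev10 <- rbind(mkAt(10, after), mkAt(10, after), mkAt(10, before))
  expect_equal(vrzExposure(ev10, led, col)$share_within_15km, 1)
})

test_that("penguin consumption equivalence is a plain unit conversion", {
  expect_equal(penguinConsumptionEquivalent(1e6), 1e5)
  expect_equal(penguinConsumptionEquivalent(0), 0)
  expect_equal(penguinConsumptionEquivalent(2.8e6), 2.8e5)
  expect_error(penguinConsumptionEquivalent(-1), ">= 0")
})

test_that("median inter-vessel distance matches brute force", {
  trA <- fishingTrack(7200)
  expect_error(medianIntervesselDistance(list(trA)), "at least 2")
  d0 <- medianIntervesselDistance(list(trA, trA), binSeconds = 3600)
  expect_true(all(d0$median_distance_km == 0))

  trB <- trA; trB$lat <- trB$lat + 0.1     # constant 0.1 degree offset
  dAB <- medianIntervesselDistance(list(trA, trB), binSeconds = 3600)
  expect_equal(dAB$median_distance_km,
               rep(0.1 * pi * 6371 / 180, nrow(dAB)), tolerance = 1e-3)

  trC <- trA; trC$lon <- trC$lon + 0.2
  d3 <- medianIntervesselDistance(list(trA, trB, trC), binSeconds = 7200)
  expect_equal(d3$n_pairs[1], 3)
  # oracle: median of the three pairwise distances at the matched time
  mid <- min(max(as.numeric(trA$timestamp)[1] + 3600,
                 as.numeric(trA$timestamp)[1]),
             max(as.numeric(trA$timestamp)))
  posAt <- function(tr) c(approx(as.numeric(tr$timestamp), tr$lat,
                                 mid, rule = 2)$y,
                          approx(as.numeric(tr$timestamp), tr$lon,
                                 mid, rule = 2)$y)
  ps <- lapply(list(trA, trB, trC), posAt)
  dd <- c(haversineKm(ps[[1]][1], ps[[1]][2], ps[[2]][1], ps[[2]][2]),
          haversineKm(ps[[1]][1], ps[[1]][2], ps[[3]][1], ps[[3]][2]),
          haversineKm(ps[[2]][1], ps[[2]][2], ps[[3]][1], ps[[3]][2]))
  expect_equal(d3$median_distance_km[1], median(dd), tolerance = 1e-9)
})

test_that("diel coverage sums to the ledger total", {
  led <- makeLedger(t0 + (0:23) * 3600, hours = 1/6)
  cov <- coverageByHour(led)
  expect_equal(nrow(cov), 24)
  expect_true(all(abs(cov$observation_hours - 1/6) < 1e-12))
  expect_equal(sum(cov$observation_hours), sum(led$observation_hours))
  night <- makeLedger(t0 + c(0, 3600), hours = 1)      # 00h and 01h UTC
  cn <- coverageByHour(night)
  expect_equal(cn$observation_hours[13], 0)            # noon empty
  expect_equal(sum(cn$observation_hours), 2)
})
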