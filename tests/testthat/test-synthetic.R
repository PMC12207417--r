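test_that("an empty scene is pure background noise", {
  sc <- simulateScene(sceneConfig(durationS = 60, maxDepthM = 50,
                                  rngSeed = 3))
  expect_true(all(maskMatrix(sc$truth) == 0L))
  expect_equal(dim(maskMatrix(sc$truth)), c(100L, 60L))
  expect_equal(nrow(truthEvents(sc$truth)), 0L)
  sv <- svMatrix(sc$record)
  expect_equal(mean(sv), -85, tolerance = 0.05)
})

test_that("scenes are bit-identical under the same configuration", {
  cfg <- corpusSceneConfig(seed = 11, durationS = 120, maxDepthM = 100,
                           nWhales = 1)
  a <- suppressWarnings(simulateScene(cfg))
  b <- suppressWarnings(simulateScene(cfg))
  expect_identical(svMatrix(a$record), svMatrix(b$record))
  expect_identical(maskMatrix(a$truth), maskMatrix(b$truth))
  expect_identical(truthEvents(a$truth), truthEvents(b$truth))
})

test_that("planted spans define event duration and height", {
  spec <- plantSpec("bubble_trail", 100, 145, 50, 80, -40,
                    shape = list(widthPx = 2))
  sc <- simulateScene(sceneConfig(durationS = 300, maxDepthM = 120,
                                  noiseMeanDb = -120, noiseSdDb = 0,
                                  objectSpecs = list(spec)))
  ev <- truthEvents(sc$truth)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 45)

  # whale footprint from 40 to 50 m spans exactly 10 m of rows
  wspec <- plantSpec("whale_dive", 100, 140, 40, 50, -33)
  sc2 <- simulateScene(sceneConfig(durationS = 300, maxDepthM = 120,
                                   noiseMeanDb = -120, noiseSdDb = 0,
                                   objectSpecs = list(wspec)))
  m <- maskMatrix(sc2$truth)
  rows <- range(which(rowSums(m == 3L) > 0))
  expect_equal((rows[2] - rows[1] + 1L) * 0.5, 10)
  expect_equal(truthEvents(sc2$truth)$height_m, 10)
})

test_that("bubble trails never exceed 2 m of local vertical width", {
  # steepest admissible trail at base width 3: ascent + width = 4 px
  spec <- plantSpec("bubble_trail", 0, 200, 50, 150, -40,
                    shape = list(widthPx = 3))
  sc <- simulateScene(sceneConfig(durationS = 200, maxDepthM = 200,
                                  noiseMeanDb = -120, noiseSdDb = 0,
                                  objectSpecs = list(spec)))
  perCol <- colSums(maskMatrix(sc$truth) == 4L)
  expect_true(all(perCol[perCol > 0] <= 4))
  # too-steep trails are rejected outright
  expect_error(plantSpec("bubble_trail", 0, 10, 0, 100, -40),
               "too steep")
})

test_that("a seafloor band labels the bottom rows for all pings", {
  spec <- plantSpec("seafloor", 0, 60, 480, 500, -25,
                    shape = list(reliefM = 0))
  sc <- simulateScene(sceneConfig(durationS = 60, maxDepthM = 500,
                                  noiseMeanDb = -120, noiseSdDb = 0,
                                  objectSpecs = list(spec)))
  m <- maskMatrix(sc$truth)
  expect_true(all(colSums(m == 1L) > 0))
  expect_true(all(m[961:1000, ] == 1L))
})

test_that("specs outside the scene extent are rejected by name", {
  sc <- simulateScene(sceneConfig(durationS = 60, maxDepthM = 50))
  bad <- plantSpec("whale_dive", 50, 80, 10, 20, -33)
  expect_error(plantObject(sc$record, sc$truth, bad),
               "whale_dive.*outside scene extent")
})

test_that("overlap precedence keeps the stronger scatterer", {
  krill <- plantSpec("krill_swarm", 10, 50, 20, 40, -62)
  whale <- plantSpec("whale_dive", 20, 40, 25, 35, -33)
  sc <- simulateScene(sceneConfig(durationS = 60, maxDepthM = 60,
                                  noiseMeanDb = -120, noiseSdDb = 0,
                                  objectSpecs = list(whale, krill)))
  m <- maskMatrix(sc$truth)
  # whale pixels survive even though krill was planted afterwards
  expect_true(sum(m == 3L) > 0)
  ctr <- m[floor(30 / 0.5) + 1L, floor(30) + 1L]  # scene centre pixel
  expect_equal(ctr, 3L)
})

test_that("planted events trace to mask footprints of their class", {
  sc <- simulateScene(recoverySceneConfig(seed = 21))
  m <- maskMatrix(sc$truth)
  ev <- truthEvents(sc$truth)
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    code <- if (ev$object_class[i] == "whale") 3L else 4L
    cols <- (floor(ev$start_s[i]) + 1):ceiling(ev$end_s[i])
    sub <- m[, cols, drop = FALSE]
    expect_gt(sum(sub == code), 0)
    # column span of the footprint equals the event duration on the 1-s grid
    expect_equal(sum(colSums(sub == code) > 0), ev$duration_s[i])
  }
})

test_that("ping dropout marks whole columns missing, never drops them", {
  cfg <- sceneConfig(durationS = 120, maxDepthM = 50, dropout = 0.3,
                     rngSeed = 5)
  sc <- simulateScene(cfg)
  sv <- svMatrix(sc$record)
  expect_equal(length(pingTimes(sc$record)), ncol(sv))
  dropped <- colSums(is.na(sv)) == nrow(sv)
  partially <- colSums(is.na(sv)) > 0 & !dropped
  expect_gt(sum(dropped), 0)
  expect_equal(sum(partially), 0)
})

test_that("dead-reckoned tracks match hand geodesy", {
  # stationary vessel stays put
  tr0 <- simulateVesselTrack(
    data.frame(durationS = 600, speedKn = 0, headingDeg = 0),
    startLat = -60, startLon = -45)
  expect_true(all(tr0$lat == -60) && all(tr0$lon == -45))

  # 3 kn north for 1 h covers 3 nmi = 5.556 km
  tr <- simulateVesselTrack(
    data.frame(durationS = 3600, speedKn = 3, headingDeg = 0),
    startLat = -60, startLon = -45)
  d <- haversineKm(tr$lat[1], tr$lon[1], tr$lat[nrow(tr)],
                   tr$lon[nrow(tr)])
  expect_equal(d, 3 * 1.852, tolerance = 1e-4)

  # mixed speeds: only the 3-kn rows pass the fishing filter
  trm <- simulateVesselTrack(
    data.frame(durationS = c(600, 600, 600), speedKn = c(0.2, 3, 8),
               headingDeg = 0), startLat = -60, startLon = -45)
  expect_setequal(unique(trm$status[trm$speed_kn == 0.2]), "stationary")
  expect_setequal(unique(trm$status[trm$speed_kn == 3]), "fishing")
  expect_setequal(unique(trm$status[trm$speed_kn == 8]), "steaming")
})

test_that("colony sets respect bounds, populations and seed", {
  b <- c(latMin = -61, latMax = -60, lonMin = -46, lonMax = -45)
  expect_equal(nrow(makeColonySet(0, b)), 0L)
  cs <- makeColonySet(3, b, populations = c(5e5, 3e5, 2e5), seed = 2)
  expect_equal(sum(cs$population), 1e6)
  expect_true(all(cs$lat >= -61 & cs$lat <= -60))
  expect_identical(cs, makeColonySet(3, b, populations = c(5e5, 3e5, 2e5),
                                     seed = 2))
  # planted populations feed the consumption equivalence downstream
  expect_equal(penguinConsumptionEquivalent(sum(cs$population)), 1e5)
})
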