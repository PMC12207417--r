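test_that("polygon extraction counts components under 8-connectivity", {
  m <- matrix(0L, 50, 50)
  expect_equal(nrow(extractDivePolygons(m)), 0)

  m[5:10, 5:10] <- 4L
  m[30:35, 30:35] <- 4L
  polys <- extractDivePolygons(m)
  expect_equal(nrow(polys), 2)
  expect_equal(polys$object_class, c("bubble_trail", "bubble_trail"))
  expect_equal(polys$col_min, c(5, 30))        # ordered by (col_min, row_min)

  # a diagonal-touching pair is one component under 8-connectivity
  d <- matrix(0L, 10, 10)
  d[3, 3] <- 4L; d[4, 4] <- 4L
  expect_equal(nrow(extractDivePolygons(d, minPixels = 1)), 1)

  # components below minPixels are dropped
  s <- matrix(0L, 10, 10); s[2, 2] <- 3L
  expect_equal(nrow(extractDivePolygons(s, minPixels = 6)), 0)
  expect_equal(nrow(extractDivePolygons(s, minPixels = 1)), 1)
})

test_that("dive measurement uses inclusive pixel spans", {
  m <- matrix(0L, 1000, 600)
  m[200:208, 100:159] <- 3L               # 60 columns, 9 rows
  m[500, 400] <- 4L                       # single pixel
  polys <- extractDivePolygons(m, minPixels = 1, echogramId = "eg1")
  ws <- as.POSIXct("2022-01-15 00:00:00", tz = "UTC")
  ev <- measureDives(polys, ws)
  whale <- ev[ev$object_class == "whale", ]
  expect_equal(whale$duration_s, 60)
  expect_equal(whale$duration_min, 1.0)
  expect_equal(whale$acoustic_height_m, 4.5)
  expect_equal(whale$timestamp, ws + 99)
  single <- ev[ev$object_class == "bubble_trail", ]
  expect_equal(single$duration_s, 1)
  expect_equal(single$acoustic_height_m, 0.5)
  # positions come from track interpolation at the event start
  tr <- fishingTrack(3600)
  ev2 <- measureDives(polys, ws, tr)
  expect_false(any(is.na(ev2$lat)))
})

test_that("acoustic-height taxonomy partitions positive heights", {
  expect_equal(classifyMammalDive(1.5), "seal_like")
  expect_equal(classifyMammalDive(10), "whale_like")
  expect_equal(classifyMammalDive(2.5), "ambiguous")
  expect_equal(classifyMammalDive(c(1.99, 2, 3)),
               c("seal_like", "ambiguous", "whale_like"))
  expect_error(classifyMammalDive(0), "positive")
  h <- runif(200, 0.01, 30)
  cls <- classifyMammalDive(h)
  expect_true(all(cls %in% c("seal_like", "ambiguous", "whale_like")))
  expect_true(all((h < 2) == (cls == "seal_like")))
  expect_true(all((h >= 3) == (cls == "whale_like")))
  # on the 0.5-m grid a seal-like signal can never exceed 4 rows
  expect_true(all(classifyMammalDive((1:3) * 0.5) == "seal_like"))
  expect_false(classifyMammalDive(5 * 0.5) == "seal_like")
})

test_that("height histograms bin half-open and conserve counts", {
  expect_equal(nrow(acousticHeightHistogram(makeEvents(
    as.POSIXct(character(0), tz = "UTC")))), 0)
  ev <- makeEvents(rep(as.POSIXct("2022-01-15", tz = "UTC"), 3))
  ev$acoustic_height_m <- c(4.5, 4.5, 10)
  h <- acousticHeightHistogram(ev, binM = 1)
  expect_equal(h$count[h$height_lo_m == 4], 2)
  expect_equal(h$count[h$height_lo_m == 10], 1)
  expect_equal(sum(h$count), 3)

  # a synthetic fleet drawn from the two modal bands shows both modes
  set.seed(6)
  n <- 400
  hts <- ifelse(runif(n) < 0.5, runif(n, 4, 5), runif(n, 9, 13))
  evf <- makeEvents(rep(as.POSIXct("2022-01-15", tz = "UTC"), n))
  evf$acoustic_height_m <- hts
  hf <- acousticHeightHistogram(evf, binM = 1)
  expect_equal(sum(hf$count), n)
  top <- hf$height_lo_m[which.max(hf$count)]
  expect_true(top >= 4 && top < 5)
  inBands <- sum(hf$count[(hf$height_lo_m >= 4 & hf$height_lo_m < 5) |
                          (hf$height_lo_m >= 9 & hf$height_lo_m < 13)])
  expect_equal(inBands, n)
})

test_that("QC removal keeps rows but excludes them downstream", {
  t0 <- as.POSIXct("2022-01-15 00:00:00", tz = "UTC")
  ev <- makeEvents(t0 + c(0, 100, 200))
  expect_identical(applyQc(ev, NULL), ev)
  expect_identical(applyQc(ev, data.frame(event_id = character(0),
                                          keep = logical(0))), ev)
  fl <- data.frame(event_id = "ev02", keep = FALSE)
  ev2 <- applyQc(ev, fl)
  expect_equal(ev2$qc_flag, c("kept", "removed", "kept"))
  expect_equal(nrow(keptEvents(ev2)), 2)
  led <- makeLedger(t0, hours = 1)
  rt <- rateTimeseries(ev2, led, binSeconds = 86400)
  bt <- rt[rt$object_class == "bubble_trail", ]
  expect_equal(bt$predator_minutes, 2)   # two kept minutes, not three
  expect_error(applyQc(ev, data.frame(event_id = "nope", keep = FALSE)),
               "unknown event ids")
})

test_that("extraction reproduces planted events within one pixel", {
  for (s in c(7, 8)) {
    sw <- sceneWindow(recoverySceneConfig(seed = 500 + s))
    sm <- referenceSegmenter(sw$window)
    ev <- measureDives(extractDivePolygons(sm, echogramId = "eg"),
                       sw$window@startTimestamp)
    te <- truthEvents(sw$scene$truth)
    expect_equal(nrow(ev), nrow(te))
    mt <- matchPlantedEvents(ev, te, sw$window@startTimestamp)
    expect_false(any(is.na(mt$duration_s)))
    expect_true(all(mt$dStart <= 1))
    expect_true(all(abs(mt$duration_s - te$duration_s) <= 1))
    expect_true(all(abs(mt$height_m - te$height_m) <= 0.5))
    # additivity: echogram minutes equal the sum of polygon durations
    expect_equal(sum(ev$duration_s), sum(te$duration_s))
  }
})
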