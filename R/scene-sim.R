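## Synthetic acoustic scenes with pixel-level ground truth.
##
## Scenes are built on the standard 1 s x 0.5 m grid (the grid the
## preprocessing chain regrids real data onto), then sampled at the
## requested ping interval to produce a RawAcousticRecord. The GroundTruth
## mask always lives on the 1 s x 0.5 m grid.

#' Scene configuration for the synthetic acoustics generator
#'
#' @param durationS scene length in seconds (> 0).
#' @param maxDepthM maximum depth in metres (> 0).
#' @param pingIntervalS nominal ping interval in seconds; may exceed 1 s,
#'   in which case downstream regridding has to interpolate.
#' @param noiseMeanDb,noiseSdDb Gaussian background noise in Sv dB
#'   (defaults -85 / 3, plausible open-water noise at 120/200 kHz). Must lie
#'   in [-120, 0] dB.
#' @param objectSpecs list of \code{\link{plantSpec}} objects to plant.
#' @param rngSeed integer seed; identical config => bit-identical scene.
#' @param pingJitter fractional jitter of the ping interval in [0, 0.9];
#'   0 gives perfectly regular pings.
#' @param dropout probability that a ping is dropped (its column set to the
#'   reserved missing marker \code{NA}).
#' @param vesselId,startTimestamp metadata copied into the record.
#' @return list of class \code{"SceneConfig"}.
#' @examples
#' cfg <- sceneConfig(durationS = 60, maxDepthM = 50, objectSpecs = list())
#' @export
sceneConfig <- function(durationS = 600, maxDepthM = 500, pingIntervalS = 1,
                        noiseMeanDb = -85, noiseSdDb = 3,
                        objectSpecs = list(), rngSeed = 1L,
                        pingJitter = 0, dropout = 0, vesselId = "SIM",
                        startTimestamp = as.POSIXct("2022-01-15 00:00:00",
                                                    tz = "UTC")) {
  if (durationS <= 0) stop("durationS must be > 0")
  if (maxDepthM <= 0) stop("maxDepthM must be > 0")
  if (pingIntervalS <= 0) stop("pingIntervalS must be > 0")
  if (noiseMeanDb < -120 || noiseMeanDb > 0)
    stop("noiseMeanDb must lie in [-120, 0] dB")
  if (noiseSdDb < 0) stop("noiseSdDb must be >= 0")
  structure(list(durationS = durationS, maxDepthM = maxDepthM,
                 pingIntervalS = pingIntervalS, noiseMeanDb = noiseMeanDb,
                 noiseSdDb = noiseSdDb, objectSpecs = objectSpecs,
                 rngSeed = as.integer(rngSeed), pingJitter = pingJitter,
                 dropout = dropout, vesselId = vesselId,
                 startTimestamp = startTimestamp),
            class = "SceneConfig")
}

#' Specification of one object to plant into a scene
#'
#' Geometry conventions: time spans are half-open \code{[startTimeS,
#' endTimeS)} seconds, depth spans half-open \code{[depthTopM,
#' depthBottomM)} metres, so a whale spec from 40 to 50 m rasterizes to a
#' footprint with a 10-m vertical extent.
#'
#' Shape parameters by class:
#' \describe{
#'   \item{krill_swarm / whale_dive}{elliptical blob spanning the given
#'     time/depth box; no extra parameters.}
#'   \item{bubble_trail}{\code{widthPx} (1-3, default 2): base vertical
#'     width of the streak in 0.5-m pixels; \code{fadeDb} (default 6):
#'     linear intensity fade from the start toward the end of the trail.
#'     The streak ascends linearly from \code{depthBottomM} at the start to
#'     \code{depthTopM} at the end. The ascent rate (in pixels per column)
#'     plus \code{widthPx} must not exceed 4, which guarantees the comet
#'     stays at most 2 m (4 pixels) high in any column while remaining
#'     8-connected.}
#'   \item{seafloor}{\code{reliefM} (default 2) and \code{reliefPeriodS}
#'     (default 300): gentle sinusoidal bottom topography added to
#'     \code{depthTopM}.}
#' }
#'
#' @param objectClass one of "krill_swarm", "bubble_trail", "whale_dive",
#'   "seafloor".
#' @param startTimeS,endTimeS time span (s), end > start.
#' @param depthTopM,depthBottomM depth span (m), bottom > top.
#' @param intensityDb Sv intensity of the object in dB; planting raises the
#'   scene's Sv to at least this value inside the footprint.
#' @param shape named list of class-specific shape parameters (see above).
#' @return list of class \code{"PlantSpec"}.
#' @examples
#' plantSpec("whale_dive", 100, 130, 40, 50, -33)
#' @export
plantSpec <- function(objectClass, startTimeS, endTimeS, depthTopM,
                      depthBottomM, intensityDb, shape = list()) {
  objectClass <- match.arg(objectClass,
    c("krill_swarm", "bubble_trail", "whale_dive", "seafloor"))
  if (endTimeS <= startTimeS) stop("endTimeS must exceed startTimeS")
  if (depthBottomM <= depthTopM) stop("depthBottomM must exceed depthTopM")
  if (objectClass == "whale_dive" && (depthBottomM - depthTopM) < 3)
    stop("whale_dive vertical extent must be >= 3 m")
  if (objectClass == "bubble_trail") {
    w <- shape$widthPx %||% 2L
    if (w < 1 || w > 3) stop("bubble_trail widthPx must be 1, 2 or 3")
    slope <- ((depthBottomM - depthTopM) / 0.5) / (endTimeS - startTimeS)
    if (slope + w > 4 + 1e-9)
      stop("bubble_trail ascent too steep: ascent rate (px/column) + widthPx",
           " must be <= 4 so the streak stays within 2 m locally")
    shape$widthPx <- as.integer(w)
    shape$fadeDb <- shape$fadeDb %||% 6
  }
  if (objectClass == "seafloor") {
    shape$reliefM <- shape$reliefM %||% 2
    shape$reliefPeriodS <- shape$reliefPeriodS %||% 300
  }
  structure(list(objectClass = objectClass, startTimeS = startTimeS,
                 endTimeS = endTimeS, depthTopM = depthTopM,
                 depthBottomM = depthBottomM, intensityDb = intensityDb,
                 shape = shape),
            class = "PlantSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Footprint of a spec on an nD x nT 1 s x 0.5 m grid: list with parallel
## vectors row, col, db (intensity per pixel).
.rasterizeSpec <- function(spec, nD, nT) {
  cols <- .colsForTime(spec$startTimeS, spec$endTimeS, nT)
  if (!length(cols)) return(list(row = integer(0), col = integer(0),
                                 db = numeric(0)))
  rows <- vector("list", length(cols))
  dbs <- vector("list", length(cols))
  cls <- spec$objectClass
  if (cls %in% c("krill_swarm", "whale_dive")) {
    tc <- (spec$startTimeS + spec$endTimeS) / 2
    a <- (spec$endTimeS - spec$startTimeS) / 2
    dc <- (spec$depthTopM + spec$depthBottomM) / 2
    b <- (spec$depthBottomM - spec$depthTopM) / 2
    for (i in seq_along(cols)) {
      t <- cols[i] - 0.5                       # column center time
      x <- (t - tc) / a
      h <- if (abs(x) >= 1) 0 else b * sqrt(1 - x * x)
      rr <- .rowsForDepth(dc - h, dc + h, nD)
      if (!length(rr)) rr <- .rowsForDepth(dc, dc + 1e-9, nD)  # keep span
      rows[[i]] <- rr
      dbs[[i]] <- rep(spec$intensityDb, length(rr))
    }
  } else if (cls == "bubble_trail") {
    w <- spec$shape$widthPx
    fade <- spec$shape$fadeDb
    t0 <- spec$startTimeS; t1 <- spec$endTimeS
    ctrRow <- function(t) {           # ascent line, in fractional rows
      f <- (t - t0) / (t1 - t0)
      d <- spec$depthBottomM + f * (spec$depthTopM - spec$depthBottomM)
      d / 0.5 + 0.5
    }
    lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
    for (i in seq_along(cols)) {
      cl <- cols[i]
      tl <- max(t0, cl - 1); tr <- min(t1, cl)
      c1 <- ctrRow(tl); c2 <- ctrRow(tr)
      r1 <- max(1L, round(min(c1, c2)) - lo)
      r2 <- min(nD, round(max(c1, c2)) + hi)
      if (r2 > r1 + 3L) r2 <- r1 + 3L   # hard 2-m (4-row) local bound
      if (r2 < r1) next
      rr <- r1:r2
      f <- ((cl - 0.5) - t0) / (t1 - t0)       # fade along the trail
      rows[[i]] <- rr
      dbs[[i]] <- rep(spec$intensityDb - fade * max(0, min(1, f)),
                      length(rr))
    }
  } else {                                     # seafloor
    relief <- spec$shape$reliefM
    period <- spec$shape$reliefPeriodS
    for (i in seq_along(cols)) {
      t <- cols[i] - 0.5
      top <- spec$depthTopM +
        relief * (1 + sin(2 * pi * t / period)) / 2
      rr <- .rowsForDepth(top, spec$depthBottomM, nD)
      rows[[i]] <- rr
      dbs[[i]] <- rep(spec$intensityDb, length(rr))
    }
  }
  n <- lengths(rows)
  list(row = unlist(rows, use.names = FALSE) %||% integer(0),
       col = rep(cols, n),
       db = unlist(dbs, use.names = FALSE) %||% numeric(0))
}

.specClassCode <- function(cls) {
  switch(cls, krill_swarm = 2L, whale_dive = 3L, bubble_trail = 4L,
         seafloor = 1L)
}

#' Plant one object into a scene
#'
#' Raises the record's Sv to the spec's intensity inside the object
#' footprint, labels the ground-truth mask, and (for predator classes)
#' appends one event to the truth event table. Overlaps between objects are
#' resolved by scatterer-strength precedence
#' whale > bubble_trail > krill_swarm > seafloor > background; an overlap
#' between two predator objects triggers a warning.
#'
#' @param record a \linkS4class{RawAcousticRecord} whose grid matches the
#'   truth mask (1 s x 0.5 m).
#' @param truth a \linkS4class{GroundTruth} for the same scene.
#' @param spec a \code{\link{plantSpec}}.
#' @return list with elements \code{record} and \code{truth}, updated.
#' @export
plantObject <- function(record, truth, spec) {
  stopifnot(is(record, "RawAcousticRecord"), is(truth, "GroundTruth"),
            inherits(spec, "PlantSpec"))
  nD <- nrow(truth@mask); nT <- ncol(truth@mask)
  if (spec$startTimeS < 0 || spec$endTimeS > nT + 1e-9 ||
      spec$depthTopM < 0 || spec$depthBottomM > nD * 0.5 + 1e-9)
    stop(sprintf("plant spec (%s, t=[%g,%g) s, d=[%g,%g) m) outside scene extent",
                 spec$objectClass, spec$startTimeS, spec$endTimeS,
                 spec$depthTopM, spec$depthBottomM))
  fp <- .rasterizeSpec(spec, nD, nT)
  if (!length(fp$row)) return(list(record = record, truth = truth))
  idxMask <- cbind(fp$row, fp$col)
  code <- .specClassCode(spec$objectClass)
  prec <- unname(.classPrecedence[classNames()[code + 1L]])
  old <- truth@mask[idxMask]
  oldPrec <- unname(.classPrecedence[classNames()[old + 1L]])
  if (code %in% c(3L, 4L) && any(old %in% c(3L, 4L)))
    warning("planted ", spec$objectClass,
            " overlaps an existing predator object; precedence applied")
  take <- prec > oldPrec
  truth@mask[idxMask[take, , drop = FALSE]] <- code

  ## record columns covering the footprint times (pings may be irregular);
  ## each ping samples its 1-s column of the rasterized footprint
  pingCols <- .timeToCol(record@pingTimes)
  if (!anyDuplicated(pingCols)) {
    j <- match(fp$col, pingCols)
    hit <- !is.na(j)
    if (any(hit)) {
      idx <- cbind(fp$row[hit], j[hit])
      record@sv[idx] <- pmax(record@sv[idx], fp$db[hit])
    }
  } else {
    byCol <- split(seq_along(fp$row), fp$col)
    for (j in seq_along(pingCols)) {
      ii <- byCol[[as.character(pingCols[j])]]
      if (is.null(ii)) next
      rr <- fp$row[ii]
      record@sv[cbind(rr, j)] <- pmax(record@sv[cbind(rr, j)], fp$db[ii])
    }
  }

  if (spec$objectClass %in% c("whale_dive", "bubble_trail")) {
    ev <- data.frame(
      event_id = nrow(truth@events) + 1L,
      object_class = if (spec$objectClass == "whale_dive") "whale"
                     else "bubble_trail",
      start_s = spec$startTimeS, end_s = spec$endTimeS,
      depth_top_m = spec$depthTopM, depth_bottom_m = spec$depthBottomM,
      duration_s = length(unique(fp$col)),
      height_m = (max(fp$row) - min(fp$row) + 1L) * 0.5,
      stringsAsFactors = FALSE)
    truth@events <- rbind(truth@events, ev)
  }
  list(record = record, truth = truth)
}

#' Simulate an acoustic scene with known ground truth
#'
#' Generates Gaussian background noise on the 1 s x 0.5 m grid, plants all
#' objects of the configuration, then samples the scene at the configured
#' ping interval (with optional jitter and ping dropout) to form the raw
#' record. Identical configuration (including \code{rngSeed}) yields a
#' bit-identical scene.
#'
#' @param config a \code{\link{sceneConfig}}.
#' @return list with elements \code{record} (\linkS4class{RawAcousticRecord})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sc <- simulateScene(sceneConfig(durationS = 60, maxDepthM = 50))
#' table(maskMatrix(sc$truth))
#' @export
simulateScene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  nT <- as.integer(round(config$durationS))
  nD <- as.integer(round(config$maxDepthM / 0.5))
  withSeed(config$rngSeed, {
    sv <- matrix(stats::rnorm(nD * nT, config$noiseMeanDb,
                              config$noiseSdDb), nrow = nD, ncol = nT)
    ## ping grid
    if (config$pingJitter > 0) {
      iv <- config$pingIntervalS *
        stats::runif(ceiling(nT / config$pingIntervalS) + 2,
                     1 - config$pingJitter, 1 + config$pingJitter)
      pt <- cumsum(c(0, iv))
      pt <- pt[pt < config$durationS]
    } else {
      pt <- seq(0, config$durationS - 1e-9, by = config$pingIntervalS)
    }
    dropped <- if (config$dropout > 0)
      stats::runif(length(pt)) < config$dropout else rep(FALSE, length(pt))

    record <- new("RawAcousticRecord",
                  sv = sv[, .timeToCol(pt), drop = FALSE],
                  pingTimes = pt,
                  depthBins = seq(0.25, by = 0.5, length.out = nD),
                  vesselId = config$vesselId,
                  startTimestamp = config$startTimestamp,
                  positions = NULL)
    truth <- new("GroundTruth",
                 mask = matrix(0L, nD, nT),
                 events = data.frame(event_id = integer(0),
                                     object_class = character(0),
                                     start_s = numeric(0), end_s = numeric(0),
                                     depth_top_m = numeric(0),
                                     depth_bottom_m = numeric(0),
                                     duration_s = numeric(0),
                                     height_m = numeric(0)))
    ## noise-only record columns were sampled before planting; plant into
    ## both the record and (via the same footprints) the truth mask
    for (spec in config$objectSpecs) {
      res <- plantObject(record, truth, spec)
      record <- res$record; truth <- res$truth
    }
    if (any(dropped)) record@sv[, dropped] <- .PAD
    list(record = record, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Random scene configurations

#' Random scene configuration calibrated to the annotated-corpus class mix
#'
#' Draws a random set of krill swarms, bubble trails, whale dives and a
#' seafloor band whose expected pixel shares match the class proportions of
#' the manually annotated echogram corpus the segmentation model is trained
#' on: about 87\% background, 10\% krill swarm, 1\% bubble trail, with
#' whales and seafloor contributing the small remainder.
#'
#' @param seed integer seed controlling both the drawn object set and, via
#'   the embedded \code{rngSeed}, the scene noise.
#' @param durationS,maxDepthM scene extent (defaults 600 s x 500 m: one
#'   standard analysis window).
#' @param krillFraction,bubbleFraction target pixel fractions for krill
#'   swarms and bubble trails.
#' @param nWhales number of whale dives to plant; their acoustic heights
#'   are drawn from the two modal bands of observed mammal dives
#'   (4-5 m and 9-13 m).
#' @param noiseMeanDb,noiseSdDb background noise parameters; set
#'   \code{noiseSdDb = 0, noiseMeanDb = -120} for a noise-free scene.
#' @param disjointPredators if TRUE, predator objects are placed with
#'   pairwise disjoint (padded) bounding boxes so that every planted event
#'   maps to exactly one connected component; used for recovery tests. If
#'   FALSE (corpus default), predators may overlap other classes and the
#'   planting precedence resolves collisions.
#' @param seafloorDepthM nominal seafloor depth (NA to omit the seafloor).
#' @param ... passed on to \code{\link{sceneConfig}}.
#' @return a \code{\link{sceneConfig}} with populated \code{objectSpecs}.
#' @examples
#' cfg <- corpusSceneConfig(seed = 7)
#' length(cfg$objectSpecs)
#' @export
corpusSceneConfig <- function(seed, durationS = 600, maxDepthM = 500,
                              krillFraction = 0.10, bubbleFraction = 0.01,
                              nWhales = 2, noiseMeanDb = -85, noiseSdDb = 3,
                              disjointPredators = FALSE,
                              seafloorDepthM = 495, ...) {
  nT <- round(durationS); nD <- round(maxDepthM / 0.5)
  nPix <- nT * nD
  withSeed(seed, {
    specs <- list()
    boxes <- list()      # occupied predator boxes: (c1,c2,r1,r2)
    addBox <- function(c1, c2, r1, r2) boxes[[length(boxes) + 1L]] <<-
      c(c1, c2, r1, r2)
    clashes <- function(c1, c2, r1, r2, pad = 4) {
      for (b in boxes)
        if (c1 - pad <= b[2] && c2 + pad >= b[1] &&
            r1 - pad <= b[4] && r2 + pad >= b[3]) return(TRUE)
      FALSE
    }

    if (!is.na(seafloorDepthM) && seafloorDepthM < maxDepthM)
      specs <- c(specs, list(plantSpec("seafloor", 0, durationS,
                                       seafloorDepthM, maxDepthM, -25,
                                       shape = list(reliefM = 2))))

    ## whale dives: heights from the two modal bands (4-5 m, 9-13 m)
    n <- 0; tries <- 0
    while (n < nWhales && tries < 200) {
      tries <- tries + 1
      h <- if (stats::runif(1) < 0.5) stats::runif(1, 4, 5)
           else stats::runif(1, 9, 13)
      dur <- stats::runif(1, 20, min(60, durationS / 2))
      t0 <- stats::runif(1, 0, durationS - dur)
      topHi <- min(300, maxDepthM - h - 10)
      topLo <- min(20, topHi / 2)
      if (topHi <= topLo) next
      top <- stats::runif(1, topLo, topHi)
      cc <- .colsForTime(t0, t0 + dur, nT)
      rr <- .rowsForDepth(top, top + h, nD)
      if (disjointPredators &&
          clashes(min(cc), max(cc), min(rr), max(rr))) next
      specs <- c(specs, list(plantSpec("whale_dive", t0, t0 + dur, top,
                                       top + h,
                                       stats::runif(1, -36, -30))))
      addBox(min(cc), max(cc), min(rr), max(rr))
      n <- n + 1
    }

    ## bubble trails until the planned pixel budget is met
    target <- bubbleFraction * nPix
    planned <- 0; tries <- 0
    while (planned < target && tries < 400) {
      tries <- tries + 1
      w <- 2L
      slope <- stats::runif(1, 0.6, 1.7)          # pixels per column
      durHi <- min(180, 0.8 * durationS)
      dur <- stats::runif(1, min(60, durHi / 2), durHi)
      botHi <- min(170, 0.85 * maxDepthM)
      bottom <- stats::runif(1, min(60, botHi / 2), botHi)
      rise <- slope * dur * 0.5
      if (bottom - rise < 2) dur <- (bottom - 2) / (slope * 0.5)
      if (dur < 20) next
      top <- bottom - slope * dur * 0.5
      t0 <- stats::runif(1, 0, durationS - dur)
      cc <- .colsForTime(t0, t0 + dur, nT)
      rr <- .rowsForDepth(top - 1, bottom + 1, nD)
      if (disjointPredators &&
          clashes(min(cc), max(cc), min(rr), max(rr))) next
      specs <- c(specs, list(plantSpec("bubble_trail", t0, t0 + dur, top,
                                       bottom, stats::runif(1, -44, -38),
                                       shape = list(widthPx = w))))
      addBox(min(cc), max(cc), min(rr), max(rr))
      planned <- planned + length(cc) * (slope + w)
    }

    ## krill swarms until the planned area budget is met (5% over-plan to
    ## absorb swarm-swarm overlap)
    target <- 1.05 * krillFraction * nPix
    planned <- 0; tries <- 0
    while (planned < target && tries < 200) {
      tries <- tries + 1
      a <- stats::runif(1, min(40, durationS / 4),
                        min(80, durationS / 2.5)) # half-duration, s
      bM <- stats::runif(1, min(8, maxDepthM / 10),
                         min(20, maxDepthM / 5))  # half-height, m
      tc <- stats::runif(1, a, durationS - a)
      dcHi <- min(maxDepthM - bM - 15, 450)
      if (dcHi <= bM + 5) next
      dc <- stats::runif(1, bM + 5, dcHi)
      specs <- c(specs, list(plantSpec("krill_swarm", tc - a, tc + a,
                                       dc - bM, dc + bM,
                                       stats::runif(1, -64, -60))))
      planned <- planned + pi * a * (bM / 0.5)   # ellipse area in pixels
    }

    sceneConfig(durationS = durationS, maxDepthM = maxDepthM,
                noiseMeanDb = noiseMeanDb, noiseSdDb = noiseSdDb,
                objectSpecs = specs,
                rngSeed = (seed * 7919L + 13L) %% .Machine$integer.max, ...)
  })
}

#' Sparse noise-free scene configuration for recovery tests
#'
#' A convenience wrapper around \code{\link{corpusSceneConfig}} that places
#' few predators with disjoint footprints on a noise-free background, so
#' that detection and measurement can be checked event by event.
#'
#' @param seed integer seed.
#' @param ... overrides passed to \code{\link{corpusSceneConfig}}.
#' @return a \code{\link{sceneConfig}}.
#' @export
recoverySceneConfig <- function(seed, ...) {
  corpusSceneConfig(seed, krillFraction = 0.04, bubbleFraction = 0.004,
                    nWhales = 2, noiseMeanDb = -120, noiseSdDb = 0,
                    disjointPredators = TRUE, ...)
}
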