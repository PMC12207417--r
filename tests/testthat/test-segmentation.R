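test_that("corpus splits are floor-sized, disjoint and exhaustive", {
  s <- splitCorpus(as.list(seq_len(1174)), 0.7, seed = 1)
  expect_length(s$train, 821)
  expect_length(s$validation, 353)

  expect_equal(lengths(splitCorpus(as.list(1:10), 0.5, seed = 2)),
               c(train = 5L, validation = 5L))
  s7 <- splitCorpus(as.list(1:7), 0.7, seed = 3)
  expect_length(s7$train, 4)                     # floor(4.9)
  expect_length(s7$validation, 3)
  got <- sort(unlist(c(s7$train, s7$validation)))
  expect_equal(got, 1:7)
  expect_identical(splitCorpus(as.list(1:7), 0.7, seed = 3), s7)
  expect_error(splitCorpus(list(), 0.7), "empty")
})

test_that("augmentation transforms image and mask identically", {
  set.seed(8)
  img <- matrix(runif(32 * 48), 32, 48)
  mask <- matrix(0L, 32, 48); mask[10:14, 20:30] <- 4L
  pair <- list(list(image = img, mask = mask))

  ident <- augmentTrainingSet(pair, multiplier = 1, seed = 1,
                              transforms = character(0))
  expect_identical(ident[[1]]$image, img)
  expect_identical(ident[[1]]$mask, mask)

  # flips permute pixels, so class counts are preserved exactly
  fl <- augmentTrainingSet(pair, multiplier = 4, seed = 2,
                           transforms = "flip")
  for (p in fl) expect_equal(sum(p$mask == 4L), sum(mask == 4L))
  expect_length(fl, 4)

  full <- augmentTrainingSet(pair, multiplier = 3, seed = 5)
  expect_length(full, 3)
  expect_identical(full,
                   augmentTrainingSet(pair, multiplier = 3, seed = 5))
  for (p in full) {
    expect_equal(dim(p$image), dim(img))
    expect_true(all(p$mask %in% 0:4))
  }
})

test_that("the built network matches a hand-computed parameter count", {
  cfg <- unetConfig(levels = 2, baseFilters = 8, bridgeWidth = 32,
                    tileSize = 64)
  m <- buildSegmenter(cfg)
  # independent closed-form conv-parameter arithmetic
  convP <- function(cin, cout, k = 3) k * k * cin * cout + cout
  enc <- c(8, 16); bridge <- 32
  expected <- convP(1, enc[1]) + convP(enc[1], enc[1]) +
    convP(enc[1], enc[2]) + convP(enc[2], enc[2]) +
    convP(enc[2], bridge) + convP(bridge, bridge) +
    convP(enc[2] + bridge, enc[2]) + convP(enc[2], enc[2]) +
    convP(enc[1] + enc[2], enc[1]) + convP(enc[1], enc[1]) +
    convP(enc[1], 5, k = 1)
  expect_equal(nParameters(m), expected)
  # default configuration carries the published training recipe
  d <- unetConfig()
  expect_equal(d$classWeights, c(1, 1, 1, 10, 1))
  expect_equal(d$tileSize, 256L)
  expect_equal(d$epochs, 100L)
  expect_equal(d$batchSize, 20L)
  expect_equal(d$levels, 4L)
  expect_equal(d$nClasses, 5L)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- unetConfig(levels = 2, baseFilters = 3, bridgeWidth = 6,
                    tileSize = 8, seed = 42)
  params <- buildSegmenter(cfg)@params
  set.seed(7)
  x <- matrix(runif(64), ncol = 1)
  y <- sample(0:4, 64, replace = TRUE); y[1:3] <- NA
  w <- cfg$classWeights
  fwd <- echodive:::.unetForward(params, x, 8, cfg, train = TRUE)
  ls <- echodive:::.softmaxLoss(fwd$logits, y, w)
  gr <- echodive:::.unetBackward(params, fwd$cache, ls$dLogits, 8, cfg)
  lossAt <- function(p)
    echodive:::.softmaxLoss(echodive:::.unetForward(p, x, 8, cfg)$logits,
                            y, w)$loss
  eps <- 1e-6
  for (nm in c("e1c1W", "e2c2W", "bc1W", "d2c1W", "d1c2W", "outW",
               "e1c1b", "outb")) {
    for (ii in sample(length(params[[nm]]), 3)) {
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossAt(p2) - lossAt(p3)) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("the weighted loss equals its per-class recomputation", {
  set.seed(12)
  logits <- matrix(rnorm(40 * 5), 40, 5)
  y <- sample(0:4, 40, replace = TRUE)
  w <- c(1, 1, 1, 10, 1)
  out <- echodive:::.softmaxLoss(logits, y, w)
  # oracle: per-pixel cross-entropy from first principles
  p <- exp(logits); p <- p / rowSums(p)
  ce <- -log(p[cbind(1:40, y + 1)])
  wi <- w[y + 1]
  expect_equal(out$loss, sum(wi * ce) / sum(wi), tolerance = 1e-12)
  # doubling the whale weight doubles whale pixels' (unnormalized)
  # contribution and leaves the others untouched
  w2 <- c(1, 1, 1, 20, 1)
  out2 <- echodive:::.softmaxLoss(logits, y, w2)
  wi2 <- w2[y + 1]
  expect_equal(out2$loss * sum(wi2) - out$loss * sum(wi),
               sum((wi2 - wi) * ce), tolerance = 1e-9)
  expect_equal(sum((wi2 - wi) * ce), sum(wi[y == 3] * ce[y == 3]),
               tolerance = 1e-9)
})

test_that("training checkpoints on validation loss and records history", {
  set.seed(3)
  mkTile <- function() {
    img <- matrix(runif(256, 0, 0.2), 16, 16)
    mask <- matrix(0L, 16, 16)
    img[6:9, 6:9] <- 0.9; mask[6:9, 6:9] <- 4L
    list(image = img, mask = mask)
  }
  train <- replicate(6, mkTile(), simplify = FALSE)
  val <- replicate(2, mkTile(), simplify = FALSE)
  cfg <- unetConfig(levels = 2, baseFilters = 4, bridgeWidth = 8,
                    tileSize = 16, epochs = 4, batchSize = 3,
                    tilesPerImage = 1, seed = 9)
  m <- buildSegmenter(cfg)
  tm <- trainSegmenter(m, train, val)
  h <- trainingHistory(tm)
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$trainLoss)))
  expect_lte(min(h$valLoss), h$valLoss[1])

  one <- trainSegmenter(m, train[1:3], val,
                        config = unetConfig(levels = 2, baseFilters = 4,
                                            bridgeWidth = 8, tileSize = 16,
                                            epochs = 1, batchSize = 3,
                                            tilesPerImage = 1, seed = 9))
  expect_equal(nrow(trainingHistory(one)), 1)
})

test_that("thresholding follows the eligibility-then-argmax rule", {
  K <- 5
  acc <- array(0, c(2, 2, K))
  acc[1, 1, ] <- c(0.9, 0.025, 0.025, 0.025, 0.025)  # clear background
  acc[1, 2, ] <- c(0.05, 0.025, 0.025, 0.3, 0.6)     # bubble beats whale
  acc[2, 1, ] <- c(0.2, 0.2, 0.2, 0.2, 0.2)          # exact tie
  acc[2, 2, ] <- c(0.55, 0.05, 0.05, 0.05, 0.3)
  th <- rep(0.5, K)
  lab <- echodive:::.thresholdProbs(acc, th)
  expect_equal(lab[1, 1], 0L)
  expect_equal(lab[1, 2], 4L)          # bubble 0.6 over threshold, whale not
  expect_equal(lab[2, 1], 0L)          # nothing eligible -> background
  expect_equal(lab[2, 2], 0L)
  # all thresholds zero degenerates to argmax, rare class wins exact ties
  lab0 <- echodive:::.thresholdProbs(acc, rep(0, K))
  expect_equal(lab0[1, 2], 4L)
  expect_equal(lab0[2, 1], 3L)         # tie -> whale by priority
  expect_equal(lab0[2, 2], 0L)
})

test_that("prediction emits simplex probabilities and padded background", {
  cfg <- unetConfig(levels = 2, baseFilters = 4, bridgeWidth = 8,
                    tileSize = 16, seed = 1)
  m <- buildSegmenter(cfg)
  img <- matrix(runif(32 * 32), 32, 32)
  img[, 1:8] <- NA                       # padded stripe
  out <- predictAndThreshold(m, img)
  p <- probArray(out$probs)
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-6))
  expect_true(all(maskMatrix(out$mask)[, 1:8] == 0L))
  # an all-padding image maps to an all-background mask
  allNA <- matrix(NA_real_, 16, 16)
  expect_true(all(maskMatrix(predictAndThreshold(m, allNA)$mask) == 0L))
})

test_that("the reference segmenter recovers noise-free planted scenes", {
  expect_true(all(maskMatrix(referenceSegmenter(
    matrix(0, 200, 100))) == 0L))

  # one 10-m whale blob -> exactly one whale component
  spec <- plantSpec("whale_dive", 20, 60, 40, 50, -33)
  sw <- sceneWindow(sceneConfig(durationS = 600, maxDepthM = 500,
                                noiseMeanDb = -120, noiseSdDb = 0,
                                objectSpecs = list(spec)))
  sm <- referenceSegmenter(sw$window)
  polys <- extractDivePolygons(sm)
  expect_equal(nrow(polys), 1)
  expect_equal(polys$object_class, "whale")

  # sparse synthetic scenes: every class at F1 >= 0.95
  cm <- matrix(0, 5, 5)
  for (s in 1:3) {
    sw <- sceneWindow(recoverySceneConfig(seed = 400 + s))
    cm <- cm + confusionCounts(referenceSegmenter(sw$window),
                               maskMatrix(sw$window))
  }
  met <- metricsFromConfusion(cm)
  expect_true(all(met$f1[met$support > 0] >= 0.95))
})

test_that("evaluation reproduces confusion-matrix arithmetic", {
  truth <- matrix(0L, 20, 20)
  truth[1, 1:10] <- 4L                   # 10 true bubble pixels
  pred <- matrix(0L, 20, 20)
  pred[1, 1:8] <- 4L                     # 8 hits
  pred[5, 1:2] <- 4L                     # 2 false positives
  rep <- evaluateSegmentation(pred, truth)
  pc <- rep@perClass
  b <- pc[pc$class == "bubble_trail", ]
  expect_equal(b$precision, 0.8)
  expect_equal(b$recall, 0.8)
  expect_equal(b$f1, 0.8)

  perfect <- evaluateSegmentation(truth, truth)
  expect_true(all(perfect@perClass$f1[perfect@perClass$support > 0] == 1))
  expect_error(evaluateSegmentation(matrix(0L, 3, 3), truth), "differ")
})

test_that("probability evaluation sweeps thresholds and picks F1 maxima", {
  set.seed(5)
  H <- 12; W <- 12
  truth <- matrix(0L, H, W); truth[4:6, 4:9] <- 4L
  acc <- array(0, c(H, W, 5))
  pB <- ifelse(truth == 4L, 0.7, 0.1) + runif(H * W, 0, 0.05)
  acc[, , 5] <- pB
  acc[, , 1] <- 1 - pB
  rep <- evaluateSegmentation(new("ProbabilityMap", probs = acc), truth)
  expect_true(nrow(rep@prCurves) > 0)
  expect_true(all(rep@prCurves$precision >= 0 & rep@prCurves$recall <= 1))
  expect_gte(rep@perClass$f1[5], 0.95)
  expect_true(rep@thresholds[["bubble_trail"]] > 0.1 &&
              rep@thresholds[["bubble_trail"]] < 0.7)
})
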