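## Configurable U-Net for five-class echogram segmentation.

#' U-Net configuration
#'
#' Defaults follow the training recipe used for the full-scale model:
#' 4 encoder-decoder levels, 256 x 256 input tiles, five classes, weighted
#' categorical cross-entropy (whale pixels weighted 10:1 against the other
#' classes), Adam, 100 epochs, batch size 20. Reduced configurations
#' (fewer levels, smaller tiles and filter counts) are used for CPU-scale
#' experiments on synthetic scenes.
#'
#' @param levels encoder-decoder depth (>= 1).
#' @param baseFilters filters in the first encoder level; doubled per level.
#' @param bridgeWidth filters in the bridge (bottleneck) convolutions.
#' @param nClasses number of output classes (5 for this pipeline).
#' @param tileSize input tile side in pixels; must be divisible by
#'   \code{2^levels}.
#' @param classWeights per-class loss weights in mask-code order
#'   (background, seafloor, krill_swarm, whale, bubble_trail).
#' @param epochs,batchSize,learningRate Adam training parameters.
#' @param tilesPerImage training tiles sampled from each image per epoch.
#' @param seed integer seed for initialization and tile sampling.
#' @return list of class \code{"UNetConfig"}.
#' @examples
#' cfg <- unetConfig(levels = 2, baseFilters = 8, bridgeWidth = 32,
#'                   tileSize = 64)
#' @export
unetConfig <- function(levels = 4, baseFilters = 16, bridgeWidth = 512,
                       nClasses = 5, tileSize = 256,
                       classWeights = c(1, 1, 1, 10, 1),
                       epochs = 100, batchSize = 20, learningRate = 1e-3,
                       tilesPerImage = 2, seed = 1L) {
  stopifnot(levels >= 1, baseFilters >= 1, bridgeWidth >= 1)
  if (nClasses != 5)
    stop("this pipeline uses exactly 5 classes (background, seafloor, ",
         "krill_swarm, whale, bubble_trail)")
  if (tileSize %% (2 ^ levels) != 0)
    stop("tileSize must be divisible by 2^levels")
  if (any(classWeights <= 0)) stop("class weights must be > 0")
  if (length(classWeights) != nClasses)
    stop("classWeights must have one entry per class")
  structure(list(levels = as.integer(levels),
                 baseFilters = as.integer(baseFilters),
                 bridgeWidth = as.integer(bridgeWidth),
                 nClasses = as.integer(nClasses),
                 tileSize = as.integer(tileSize),
                 classWeights = classWeights, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 tilesPerImage = as.integer(tilesPerImage),
                 optimizer = "adam",
                 loss = "weighted_categorical_crossentropy",
                 seed = as.integer(seed)),
            class = c("UNetConfig", "list"))
}

## channel plan: encoder level l has baseFilters * 2^(l-1) filters
.unetChannels <- function(cfg) {
  enc <- cfg$baseFilters * 2 ^ (seq_len(cfg$levels) - 1)
  list(enc = enc, bridge = cfg$bridgeWidth)
}

.heInit <- function(nin, nout, fanIn) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fanIn)), nin, nout)
}

.unetInitParams <- function(cfg) {
  ch <- .unetChannels(cfg)
  L <- cfg$levels
  p <- list()
  add <- function(nm, cin, cout, k = 9L) {
    p[[paste0(nm, "W")]] <<- .heInit(k * cin, cout, k * cin)
    p[[paste0(nm, "b")]] <<- numeric(cout)
  }
  cin <- 1L
  for (l in seq_len(L)) {
    add(sprintf("e%dc1", l), cin, ch$enc[l])
    add(sprintf("e%dc2", l), ch$enc[l], ch$enc[l])
    cin <- ch$enc[l]
  }
  add("bc1", cin, ch$bridge)
  add("bc2", ch$bridge, ch$bridge)
  below <- ch$bridge
  for (l in rev(seq_len(L))) {
    add(sprintf("d%dc1", l), ch$enc[l] + below, ch$enc[l])
    add(sprintf("d%dc2", l), ch$enc[l], ch$enc[l])
    below <- ch$enc[l]
  }
  add("out", ch$enc[1], cfg$nClasses, k = 1L)
  p
}

#' Build an untrained segmentation network
#'
#' Constructs the U-Net described by the configuration: per encoder level
#' two 3x3 convolutions (ReLU) followed by 2x2 max-pooling, a two-convolution
#' bridge, and a mirrored decoder with nearest-neighbour upsampling and skip
#' concatenation, closed by a 1x1 convolution onto the five class logits.
#' Weights use He-normal initialization under the configuration seed.
#'
#' @param config a \code{\link{unetConfig}}.
#' @return an untrained \linkS4class{UNetModel}; the trainable parameter
#'   count is available via \code{\link{nParameters}}.
#' @examples
#' m <- buildSegmenter(unetConfig(levels = 2, baseFilters = 4,
#'                                bridgeWidth = 16, tileSize = 32))
#' nParameters(m)
#' @export
buildSegmenter <- function(config) {
  stopifnot(inherits(config, "UNetConfig"))
  params <- withSeed(config$seed, .unetInitParams(config))
  n <- sum(vapply(params, length, numeric(1)))
  new("UNetModel", config = config, params = params,
      history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                           valLoss = numeric(0)),
      nParams = as.integer(n))
}

## Forward pass on one tile. x: HW x 1 matrix (NA already zeroed).
## Returns logits and, when train=TRUE, the cache for backprop.
.unetForward <- function(params, x, S, cfg, train = FALSE, Sw = S) {
  L <- cfg$levels
  cache <- list()
  cur <- x; h <- S; w <- Sw
  for (l in seq_len(L)) {
    nm <- sprintf("e%dc1", l)
    cf <- .convFwd(cur, h, w, params[[paste0(nm, "W")]],
                   params[[paste0(nm, "b")]], cache = train)
    a1 <- pmax(cf$Y, 0)
    if (train) cache[[nm]] <- list(Xin = cf$Xin, pre = cf$Y,
                                   cin = ncol(cur), h = h, w = w)
    nm <- sprintf("e%dc2", l)
    cf <- .convFwd(a1, h, w, params[[paste0(nm, "W")]],
                   params[[paste0(nm, "b")]], cache = train)
    a2 <- pmax(cf$Y, 0)
    if (train) cache[[nm]] <- list(Xin = cf$Xin, pre = cf$Y,
                                   cin = ncol(a1), h = h, w = w)
    cache[[sprintf("skip%d", l)]] <- a2
    pf <- .poolFwd(a2, h, w)
    if (train) cache[[sprintf("pool%d", l)]] <- pf
    cur <- pf$Y
    h <- h %/% 2L; w <- w %/% 2L
  }
  for (nm in c("bc1", "bc2")) {
    cf <- .convFwd(cur, h, w, params[[paste0(nm, "W")]],
                   params[[paste0(nm, "b")]], cache = train)
    a <- pmax(cf$Y, 0)
    if (train) cache[[nm]] <- list(Xin = cf$Xin, pre = cf$Y,
                                   cin = ncol(cur), h = h, w = w)
    cur <- a
  }
  for (l in rev(seq_len(L))) {
    up <- .upFwd(cur, h, w)
    if (train) cache[[sprintf("upch%d", l)]] <- ncol(cur)
    h <- h * 2L; w <- w * 2L
    skip <- cache[[sprintf("skip%d", l)]]
    cur <- cbind(skip, up)
    nm <- sprintf("d%dc1", l)
    cf <- .convFwd(cur, h, w, params[[paste0(nm, "W")]],
                   params[[paste0(nm, "b")]], cache = train)
    a1 <- pmax(cf$Y, 0)
    if (train) cache[[nm]] <- list(Xin = cf$Xin, pre = cf$Y,
                                   cin = ncol(cur), h = h, w = w)
    nm <- sprintf("d%dc2", l)
    cf <- .convFwd(a1, h, w, params[[paste0(nm, "W")]],
                   params[[paste0(nm, "b")]], cache = train)
    cur <- pmax(cf$Y, 0)
    if (train) cache[[nm]] <- list(Xin = cf$Xin, pre = cf$Y,
                                   cin = ncol(a1), h = h, w = w)
  }
  logits <- cur %*% params$outW + rep(params$outb, each = nrow(cur))
  if (train) cache$outIn <- cur
  list(logits = logits, cache = cache)
}

## Backward pass; dLogits from .softmaxLoss. Returns flat grad list.
.unetBackward <- function(params, cache, dLogits, S, cfg) {
  L <- cfg$levels
  g <- list()
  g$outW <- crossprod(cache$outIn, dLogits)
  g$outb <- colSums(dLogits)
  d <- dLogits %*% t(params$outW)

  convBack <- function(nm, d) {
    cc <- cache[[nm]]
    d <- d * (cc$pre > 0)
    bw <- .convBwd(d, cc$Xin, params[[paste0(nm, "W")]], cc$h, cc$w, cc$cin)
    g[[paste0(nm, "W")]] <<- bw$dW
    g[[paste0(nm, "b")]] <<- bw$db
    bw$dX
  }

  h <- S; w <- S   # at decoder output resolution per level
  for (l in seq_len(L)) {
    hl <- S %/% (2 ^ (l - 1)); wl <- hl
    d <- convBack(sprintf("d%dc2", l), d)
    d <- convBack(sprintf("d%dc1", l), d)
    nSkip <- ncol(cache[[sprintf("skip%d", l)]])
    dSkip <- d[, seq_len(nSkip), drop = FALSE]
    dUp <- d[, nSkip + seq_len(cache[[sprintf("upch%d", l)]]),
             drop = FALSE]
    d <- .upBwd(dUp, hl %/% 2L, wl %/% 2L)
    cache[[sprintf("dskip%d", l)]] <- dSkip
  }
  d2 <- convBack("bc2", d)
  d2 <- convBack("bc1", d2)
  d <- d2
  for (l in rev(seq_len(L))) {
    hl <- S %/% (2 ^ (l - 1)); wl <- hl
    d <- .poolBwd(d, cache[[sprintf("pool%d", l)]], hl, wl)
    d <- d + cache[[sprintf("dskip%d", l)]]
    d <- convBack(sprintf("e%dc2", l), d)
    d <- convBack(sprintf("e%dc1", l), d)
  }
  g
}

## Normalize a training element into list(image=matrix, mask=int matrix).
.asImagePair <- function(x) {
  if (is(x, "Echogram")) {
    if (!length(x@truth))
      stop("training echogram has no attached truth mask")
    return(list(image = x@image, mask = x@truth))
  }
  if (is.list(x) && !is.null(x$image) && !is.null(x$mask)) return(x)
  stop("training items must be Echogram objects with truth masks or ",
       "lists with elements image and mask")
}

## Sample one tile; biased toward predator pixels half of the time so the
## rare classes are actually seen during training.
.sampleTile <- function(img, mask, S, predBias = 0.5) {
  H <- nrow(img); W <- ncol(img)
  if (H < S || W < S) stop("image smaller than tile size")
  r0 <- NULL
  u <- stats::runif(1)
  pp <- if (u < predBias) {
    which(mask == 3L | mask == 4L)          # centre on a predator pixel
  } else if (u < predBias + (1 - predBias) / 2) {
    which(mask != 0L)                       # centre on any foreground
  } else integer(0)
  if (length(pp)) {
    p <- pp[sample.int(length(pp), 1)]
    pr <- ((p - 1L) %% H) + 1L
    pc <- ((p - 1L) %/% H) + 1L
    r0 <- min(max(1L, pr - S %/% 2L), H - S + 1L)
    c0 <- min(max(1L, pc - S %/% 2L), W - S + 1L)
  }
  if (is.null(r0)) {
    r0 <- sample.int(H - S + 1L, 1)
    c0 <- sample.int(W - S + 1L, 1)
  }
  rows <- r0:(r0 + S - 1L); cols <- c0:(c0 + S - 1L)
  im <- img[rows, cols]
  mk <- mask[rows, cols]
  mk[is.na(im)] <- NA_integer_   # padding excluded from the loss
  im[is.na(im)] <- 0
  list(x = matrix(as.vector(im), ncol = 1), y = as.vector(mk))
}

#' Train a segmentation network
#'
#' Minimizes the class-weighted categorical cross-entropy with Adam over
#' tiles sampled from the training images (half of the tiles are centred on
#' predator pixels so the rare classes are represented). After each epoch
#' the validation loss is computed on a fixed set of validation tiles and
#' the parameters achieving the best validation loss are returned.
#'
#' @param model an untrained (or previously trained) \linkS4class{UNetModel}.
#' @param train,val lists of \linkS4class{Echogram} objects with truth
#'   masks, or lists with elements \code{image} and \code{mask}.
#' @param config optional \code{\link{unetConfig}} overriding the model's.
#' @param verbose print per-epoch losses.
#' @return a trained \linkS4class{UNetModel}; per-epoch losses are in
#'   \code{\link{trainingHistory}}.
#' @export
trainSegmenter <- function(model, train, val, config = NULL,
                           verbose = FALSE) {
  stopifnot(is(model, "UNetModel"))
  cfg <- if (is.null(config)) model@config else config
  if (!length(train) || !length(val))
    stop("train and val must be nonempty")
  train <- lapply(train, .asImagePair)
  val <- lapply(val, .asImagePair)
  S <- cfg$tileSize
  params <- model@params
  state <- .adamInit(params)
  bestParams <- params
  bestVal <- Inf
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0))
  ## fixed validation tiles
  valTiles <- withSeed(cfg$seed + 1L,
    lapply(val, function(p) .sampleTile(p$image, p$mask, S, predBias = 1)))
  t0 <- 0L
  for (ep in seq_len(cfg$epochs)) {
    tiles <- withSeed(cfg$seed + 1000L + ep, {
      tl <- list()
      for (p in train)
        for (k in seq_len(cfg$tilesPerImage))
          tl[[length(tl) + 1L]] <- .sampleTile(p$image, p$mask, S)
      tl[sample.int(length(tl))]
    })
    epLoss <- 0; nb <- 0L
    for (b0 in seq(1, length(tiles), by = cfg$batchSize)) {
      batch <- tiles[b0:min(length(tiles), b0 + cfg$batchSize - 1L)]
      acc <- NULL; bl <- 0
      for (tl in batch) {
        fw <- .unetForward(params, tl$x, S, cfg, train = TRUE)
        ls <- .softmaxLoss(fw$logits, tl$y, cfg$classWeights)
        gr <- .unetBackward(params, fw$cache, ls$dLogits, S, cfg)
        bl <- bl + ls$loss
        if (is.null(acc)) acc <- gr
        else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      bl <- bl / length(batch)
      if (!is.finite(bl))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; consider lowering the learning rate")
      t0 <- t0 + 1L
      up <- .adamStep(params, acc, state, cfg$learningRate, t0)
      params <- up$params; state <- up$state
      epLoss <- epLoss + bl; nb <- nb + 1L
    }
    vl <- mean(vapply(valTiles, function(tl) {
      fw <- .unetForward(params, tl$x, S, cfg, train = FALSE)
      .softmaxLoss(fw$logits, tl$y, cfg$classWeights)$loss
    }, numeric(1)))
    if (vl < bestVal) { bestVal <- vl; bestParams <- params }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss / nb,
                                   valLoss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                      epLoss / nb, vl))
  }
  new("UNetModel", config = cfg, params = bestParams, history = hist,
      nParams = model@nParams)
}

#' Predict class probabilities and a thresholded mask for an echogram
#'
#' The echogram is covered with overlapping tiles of the configured size,
#' per-tile softmax probabilities are averaged where tiles overlap, and each
#' pixel is assigned the highest-probability class among those whose
#' probability exceeds their class threshold; if no class passes, the pixel
#' is background. Exact probability ties are broken by class priority
#' whale > bubble_trail > krill_swarm > seafloor > background (rarest class
#' wins). Padding pixels are always background. With all thresholds at 0
#' the rule degenerates to argmax labelling.
#'
#' @param model a trained \linkS4class{UNetModel}.
#' @param echogram an \linkS4class{Echogram} or a grayscale matrix whose
#'   sides are at least the tile size.
#' @param thresholds numeric vector of 5 per-class probabilities in [0,1]
#'   (mask-code order).
#' @return list with elements \code{probs} (\linkS4class{ProbabilityMap})
#'   and \code{mask} (\linkS4class{SegmentationMask}).
#' @export
predictAndThreshold <- function(model, echogram,
                                thresholds = rep(0, 5)) {
  stopifnot(is(model, "UNetModel"))
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  img <- if (is(echogram, "Echogram")) echogram@image else echogram
  H <- nrow(img); W <- ncol(img)
  cfg <- model@config
  S <- cfg$tileSize
  if (H < S || W < S) stop("echogram smaller than the tile size")
  pad <- is.na(img)
  x <- img; x[pad] <- 0
  ## inference tiles can be much larger than the training tile: one
  ## forward pass per block is far cheaper than many small tiles
  blk <- 2L ^ cfg$levels
  th <- min(H %/% blk * blk, max(S, 640L %/% blk * blk))
  tw <- min(W %/% blk * blk, max(S, 640L %/% blk * blk))
  starts <- function(n, s) unique(c(seq(1L, n - s + 1L, by = s),
                                    n - s + 1L))
  acc <- array(0, c(H, W, cfg$nClasses))
  cnt <- matrix(0, H, W)
  for (r0 in starts(H, th)) for (c0 in starts(W, tw)) {
    rows <- r0:(r0 + th - 1L); cols <- c0:(c0 + tw - 1L)
    tile <- matrix(as.vector(x[rows, cols]), ncol = 1)
    fw <- .unetForward(model@params, tile, th, cfg, train = FALSE,
                      Sw = tw)
    p <- .softmaxProbs(fw$logits)
    for (k in seq_len(cfg$nClasses))
      acc[rows, cols, k] <- acc[rows, cols, k] +
        matrix(p[, k], th, tw)
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  for (k in seq_len(cfg$nClasses)) acc[, , k] <- acc[, , k] / cnt
  probs <- new("ProbabilityMap", probs = acc)
  mask <- .thresholdProbs(acc, thresholds)
  mask[pad] <- 0L
  list(probs = probs,
       mask = new("SegmentationMask", labels = mask, provenance = "model"))
}

## Shared thresholding rule: eligible classes (p >= threshold) competed by
## probability; ties and the argmax order follow rarity priority.
.thresholdProbs <- function(acc, thresholds) {
  H <- dim(acc)[1]; W <- dim(acc)[2]
  prio <- c(3L, 4L, 2L, 1L, 0L)     # whale, bubble, krill, seafloor, bg
  P <- matrix(0, H * W, length(prio))
  for (i in seq_along(prio)) {
    k <- prio[i] + 1L
    p <- as.vector(acc[, , k])
    p[p < thresholds[k]] <- -1      # ineligible
    P[, i] <- p
  }
  best <- max.col(P, ties.method = "first")
  lab <- prio[best]
  lab[P[cbind(seq_len(H * W), best)] < 0] <- 0L   # none eligible
  matrix(as.integer(lab), H, W)
}
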