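## Corpus handling, augmentation, the rule-based reference segmenter, and
## segmentation evaluation.

#' EvaluationReport: per-class segmentation metrics
#'
#' @slot perClass data.frame with columns class, precision, recall, f1,
#'   accuracy, support (truth pixel count).
#' @slot overallAccuracy numeric scalar.
#' @slot prCurves data.frame of threshold sweeps (empty when evaluated from
#'   a hard mask).
#' @slot thresholds named numeric vector of selected per-class thresholds
#'   (empty when evaluated from a hard mask).
#' @export
setClass("EvaluationReport",
  representation(perClass = "data.frame", overallAccuracy = "numeric",
                 prCurves = "data.frame", thresholds = "numeric"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (overall accuracy",
      round(object@overallAccuracy, 4), ")\n")
  print(object@perClass, row.names = FALSE, digits = 4)
})

#' Split a corpus into training and validation sets
#'
#' @param images list (or vector) of corpus items.
#' @param trainFraction fraction assigned to training, in (0, 1); the
#'   training size is \code{floor(trainFraction * n)}.
#' @param seed integer seed; the split is deterministic under it.
#' @return list with elements \code{train} and \code{validation}; the two
#'   partitions are disjoint and exhaustive.
#' @examples
#' s <- splitCorpus(as.list(1:1174), 0.7, seed = 1)
#' lengths(s)  # 821 / 353
#' @export
splitCorpus <- function(images, trainFraction, seed = 1L) {
  n <- length(images)
  if (n == 0) stop("corpus is empty")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  nTrain <- floor(trainFraction * n)
  idx <- withSeed(seed, sample.int(n, nTrain))
  list(train = images[idx],
       validation = images[setdiff(seq_len(n), idx)])
}

## bilinear / nearest warp of a matrix by absolute source coordinates
.warp <- function(m, srcR, srcC, nearest = FALSE, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  sR <- as.vector(srcR); sC <- as.vector(srcC)
  if (nearest) {
    r <- round(sR); cc <- round(sC)
    ok <- r >= 1 & r <= H & cc >= 1 & cc <= W
    out <- rep(fill, length(sR))
    out[ok] <- m[cbind(r[ok], cc[ok])]
  } else {
    r0 <- floor(sR); c0 <- floor(sC)
    fr <- sR - r0; fc <- sC - c0
    r0 <- pmin(pmax(r0, 1), H); r1 <- pmin(r0 + 1, H)
    c0 <- pmin(pmax(c0, 1), W); c1 <- pmin(c0 + 1, W)
    ok <- sR >= 1 & sR <= H & sC >= 1 & sC <= W
    out <- rep(fill, length(sR))
    v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
         m[cbind(r1, c0)] * fr * (1 - fc) +
         m[cbind(r0, c1)] * (1 - fr) * fc +
         m[cbind(r1, c1)] * fr * fc
    out[ok] <- v[ok]
  }
  matrix(out, nrow(srcR), ncol(srcR))
}

.augmentOne <- function(img, mask, transforms, cropScale = c(0.6, 1),
                        maxRotate = 15, elasticAlpha = 15,
                        elasticSigma = 4) {
  img[is.na(img)] <- 0
  if ("flip" %in% transforms) {
    if (stats::runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img)))]
                                 mask <- mask[, rev(seq_len(ncol(mask)))] }
    if (stats::runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), ]
                                 mask <- mask[rev(seq_len(nrow(mask))), ] }
  }
  H <- nrow(img); W <- ncol(img)
  if ("crop" %in% transforms) {
    u <- stats::runif(1, cropScale[1], cropScale[2])
    h <- max(2L, round(u * H)); w <- max(2L, round(u * W))
    r0 <- sample.int(H - h + 1L, 1); c0 <- sample.int(W - w + 1L, 1)
    sub <- img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    subM <- mask[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    ## resample back to the original size
    srcR <- matrix(seq(1, h, length.out = H), H, W)
    srcC <- matrix(rep(seq(1, w, length.out = W), each = H), H, W)
    img <- .warp(sub, srcR, srcC)
    mask <- matrix(as.integer(.warp(subM, srcR, srcC, nearest = TRUE)),
                   H, W)
  }
  if ("rotate" %in% transforms) {
    th <- stats::runif(1, -maxRotate, maxRotate) * pi / 180
    rc <- (H + 1) / 2; ccn <- (W + 1) / 2
    g <- expand.grid(r = seq_len(H), c = seq_len(W))
    dr <- g$r - rc; dc <- g$c - ccn
    srcR <- matrix(rc + cos(th) * dr - sin(th) * dc, H, W)
    srcC <- matrix(ccn + sin(th) * dr + cos(th) * dc, H, W)
    img <- .warp(img, srcR, srcC)
    mask <- matrix(as.integer(.warp(mask, srcR, srcC, nearest = TRUE)),
                   H, W)
  }
  if ("elastic" %in% transforms) {
    dR <- EBImage::gblur(matrix(stats::runif(H * W, -1, 1), H, W),
                         sigma = elasticSigma) * elasticAlpha
    dC <- EBImage::gblur(matrix(stats::runif(H * W, -1, 1), H, W),
                         sigma = elasticSigma) * elasticAlpha
    base <- expand.grid(r = seq_len(H), c = seq_len(W))
    srcR <- matrix(base$r, H, W) + dR
    srcC <- matrix(base$c, H, W) + dC
    img <- .warp(img, srcR, srcC)
    mask <- matrix(as.integer(.warp(mask, srcR, srcC, nearest = TRUE)),
                   H, W)
  }
  list(image = img, mask = mask)
}

#' Augment a training set of image/mask pairs
#'
#' Each output is a randomly transformed copy of an input pair, with the
#' identical geometric transform applied to image and mask (masks use
#' nearest-neighbour resampling so labels stay categorical). Available
#' transform families: random crops (rescaled back), horizontal/vertical
#' flips, small rotations, and elastic deformations.
#'
#' @param train list of \linkS4class{Echogram} objects with truth masks or
#'   lists with \code{image} and \code{mask}.
#' @param multiplier output size = multiplier x input size (>= 1).
#' @param seed integer seed; deterministic under it.
#' @param transforms character subset of c("crop", "flip", "rotate",
#'   "elastic"); an empty vector yields identity copies.
#' @return list of lists with elements \code{image} and \code{mask}.
#' @export
augmentTrainingSet <- function(train, multiplier = 1, seed = 1L,
                               transforms = c("crop", "flip", "rotate",
                                              "elastic")) {
  if (multiplier < 1) stop("multiplier must be >= 1")
  pairs <- lapply(train, .asImagePair)
  withSeed(seed, {
    out <- vector("list", length(pairs) * multiplier)
    i <- 0L
    for (rep in seq_len(multiplier)) for (p in pairs) {
      i <- i + 1L
      out[[i]] <- if (length(transforms))
        .augmentOne(p$image, p$mask, transforms) else p
    }
    out
  })
}

## 8-connected component labelling. EBImage::bwlabel is 4-connected, so
## labels touching diagonally are merged with a small union-find.
.labelComponents <- function(bin, connectivity = 8) {
  bin[is.na(bin)] <- FALSE
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  nl <- max(lab)
  if (connectivity == 4 || nl < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]          # down-right diagonal
  a2 <- lab[-1, -W]; b2 <- lab[-H, -1]          # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                        cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs)) {
    parent <- seq_len(nl)
    find <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]
                               x <- parent[x] }
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nl), find, integer(1))
    compact <- match(root, sort(unique(root)))
    nz <- lab > 0
    lab[nz] <- compact[lab[nz]]
  }
  lab
}

#' Rule-based reference segmenter
#'
#' A deterministic segmenter built from simple acoustic rules, used as an
#' independent stand-in for the trained network on synthetic scenes and for
#' production runs where a trained model is not wanted. Pixels above a
#' strong intensity cut form candidate seafloor/predator components; pixels
#' in a weaker band form krill-swarm candidates. Components are classified
#' by geometry: a deep band spanning most of the record is seafloor; a
#' narrow (locally <= 2 m) ascending streak is a bubble trail; a compact
#' signal at least 3 m high is a whale; anything else falls back to krill
#' swarm. Components smaller than \code{minPx} pixels are discarded.
#'
#' @param echogram an \linkS4class{Echogram} or grayscale matrix in [0,1].
#' @param strongCutDb Sv cut (dB) for predator/seafloor candidates.
#' @param weakCutDb Sv cut (dB) for krill candidates.
#' @param minPx minimum component size in pixels.
#' @return a \linkS4class{SegmentationMask} with provenance "reference".
#' @export
referenceSegmenter <- function(echogram, strongCutDb = -55,
                               weakCutDb = -72, minPx = 6) {
  img <- if (is(echogram, "Echogram")) echogram@image else echogram
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0L, H, W)
  gS <- svToGrayscale(strongCutDb)
  gW <- svToGrayscale(weakCutDb)
  valid <- !is.na(img)
  dataCols <- sum(colSums(valid) > 0)
  if (dataCols == 0)
    return(new("SegmentationMask", labels = out, provenance = "reference"))

  strong <- valid & img >= gS
  labS <- .labelComponents(strong)
  if (max(labS) > 0) {
    pix <- which(labS > 0)
    comp <- labS[pix]
    rows <- ((pix - 1L) %% H) + 1L
    cols <- ((pix - 1L) %/% H) + 1L
    for (id in seq_len(max(labS))) {
      sel <- comp == id
      if (sum(sel) < minPx) next
      r <- rows[sel]; cc <- cols[sel]
      colspan <- max(cc) - min(cc) + 1L
      rowspan <- max(r) - min(r) + 1L
      perCol <- tabulate(cc - min(cc) + 1L, nbins = colspan)
      wmax <- max(perCol)
      cls <- if (colspan >= 0.8 * dataCols && min(r) > H / 2) {
        1L                                       # seafloor band
      } else if (wmax <= 4L) {
        ## narrow streak: bubble trail if ascending, else krill
        mr <- tapply(r, cc, mean)
        asc <- if (length(mr) >= 5)
          stats::cor(as.numeric(names(mr)), as.numeric(mr)) else 0
        if (is.na(asc)) asc <- 0
        if (asc <= -0.2 || colspan < 5) 4L else 2L
      } else if (rowspan >= 6L) {
        3L                                       # whale: >= 3 m tall
      } else 2L
      out[pix[sel]] <- cls
    }
  }

  weak <- valid & img >= gW & img < gS
  labW <- .labelComponents(weak)
  if (max(labW) > 0) {
    sz <- tabulate(labW[labW > 0])
    keep <- which(sz >= minPx)
    sel <- labW > 0 & labW %in% keep & out == 0L
    out[sel] <- 2L
  }
  new("SegmentationMask", labels = out, provenance = "reference")
}

#' Per-class confusion counts between two masks
#'
#' @param pred,truth SegmentationMask objects or integer matrices of equal
#'   shape.
#' @return 5 x 5 matrix of pixel counts; rows = truth class, columns =
#'   predicted class.
#' @export
confusionCounts <- function(pred, truth) {
  p <- if (is(pred, "SegmentationMask")) pred@labels else pred
  t <- if (is(truth, "SegmentationMask")) truth@labels else
       if (is(truth, "GroundTruth")) truth@mask else truth
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth shapes differ: ",
         paste(dim(p), collapse = "x"), " vs ",
         paste(dim(t), collapse = "x"))
  K <- length(classCodes())
  cm <- table(factor(as.vector(t), levels = 0:(K - 1)),
              factor(as.vector(p), levels = 0:(K - 1)))
  m <- matrix(as.numeric(cm), K, K,
              dimnames = list(truth = classNames(), pred = classNames()))
  m
}

#' Precision/recall/F1/accuracy from a confusion matrix
#'
#' F1 is \code{2PR/(P+R)} with the 0/0 case defined as 0.
#'
#' @param cm 5 x 5 confusion matrix (rows = truth, columns = predicted).
#' @return data.frame with one row per class.
#' @export
metricsFromConfusion <- function(cm) {
  K <- nrow(cm)
  N <- sum(cm)
  res <- data.frame(class = rownames(cm), precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, accuracy = NA_real_,
                    support = rowSums(cm), stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
    tn <- N - tp - fp - fn
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$precision[k] <- p
    res$recall[k] <- r
    res$f1[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    res$accuracy[k] <- (tp + tn) / N
  }
  rownames(res) <- NULL
  res
}

#' Evaluate a segmentation against truth
#'
#' Given a hard mask, computes per-class pixel precision, recall, F1 and
#' one-vs-rest accuracy. Given a \linkS4class{ProbabilityMap}, additionally
#' sweeps per-class probability thresholds to produce precision-recall
#' curves and selects the F1-maximizing threshold per class.
#'
#' @param pred a \linkS4class{SegmentationMask}, integer matrix, or
#'   \linkS4class{ProbabilityMap}.
#' @param truth a \linkS4class{SegmentationMask}, \linkS4class{GroundTruth}
#'   or integer matrix.
#' @param thresholdGrid thresholds swept for probability input.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateSegmentation <- function(pred, truth,
                                 thresholdGrid = seq(0.05, 0.95,
                                                     by = 0.05)) {
  tm <- if (is(truth, "SegmentationMask")) truth@labels else
        if (is(truth, "GroundTruth")) truth@mask else truth
  if (is(pred, "ProbabilityMap")) {
    acc <- pred@probs
    if (!identical(dim(acc)[1:2], dim(tm)))
      stop("probability map and truth shapes differ")
    K <- length(classCodes())
    tv <- as.vector(tm)
    curves <- list()
    best <- numeric(K)
    for (k in seq_len(K)) {
      pk <- as.vector(acc[, , k])
      isK <- tv == (k - 1L)
      rows <- lapply(thresholdGrid, function(th) {
        sel <- pk >= th
        tp <- sum(sel & isK); fp <- sum(sel & !isK); fn <- sum(!sel & isK)
        p <- if (tp + fp > 0) tp / (tp + fp) else 0
        r <- if (tp + fn > 0) tp / (tp + fn) else 0
        data.frame(class = classNames()[k], threshold = th, precision = p,
                   recall = r,
                   f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
      })
      cv <- do.call(rbind, rows)
      curves[[k]] <- cv
      best[k] <- cv$threshold[which.max(cv$f1)]
    }
    names(best) <- classNames()
    mask <- .thresholdProbs(acc, best)
    cm <- confusionCounts(mask, tm)
    return(new("EvaluationReport", perClass = metricsFromConfusion(cm),
               overallAccuracy = sum(diag(cm)) / sum(cm),
               prCurves = do.call(rbind, curves), thresholds = best))
  }
  cm <- confusionCounts(pred, tm)
  new("EvaluationReport", perClass = metricsFromConfusion(cm),
      overallAccuracy = sum(diag(cm)) / sum(cm),
      prCurves = data.frame(), thresholds = numeric(0))
}
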