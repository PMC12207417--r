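## Minimal convolutional network engine used by the U-Net segmenter.
##
## Activations are stored as (H*W) x C matrices (column-major spatial
## flattening). All heavy lifting is BLAS matrix multiplication via an
## im2col layout; index maps are cached per spatial size.

.idxCache <- new.env(parent = emptyenv())

.getIdx <- function(H, W) {
  key <- paste0(H, "x", W)
  got <- .idxCache[[key]]
  if (!is.null(got)) return(got)
  HW <- H * W
  p <- seq_len(HW)
  r <- ((p - 1L) %% H) + 1L
  cc <- ((p - 1L) %/% H) + 1L
  out <- list()
  if (H %% 2L == 0L && W %% 2L == 0L) {
    h <- H %/% 2L; w <- W %/% 2L
    sp <- seq_len(h * w)
    sr <- ((sp - 1L) %% h) + 1L
    sc <- ((sp - 1L) %/% h) + 1L
    out$pool <- list(
      i00 = (2L * sr - 1L) + H * (2L * sc - 2L),
      i10 = (2L * sr)      + H * (2L * sc - 2L),
      i01 = (2L * sr - 1L) + H * (2L * sc - 1L),
      i11 = (2L * sr)      + H * (2L * sc - 1L))
    ## map from each pixel of the H x W grid to its source on the h x w grid
    out$up <- ((r + 1L) %/% 2L) + h * (((cc + 1L) %/% 2L) - 1L)
  }
  .idxCache[[key]] <- out
  out
}

## 3x3 convolution: the hot path lives in compiled code (src/conv.cpp);
## these wrappers keep the cache the backward pass needs.
.convFwd <- function(X, H, W, Wm, b, cache = TRUE) {
  Y <- .cppConvFwd(X, H, W, Wm, b)
  if (cache) list(Y = Y, Xin = X) else list(Y = Y)
}

.convBwd <- function(dY, Xin, Wm, H, W, Cin) {
  .cppConvBwd(Xin, dY, H, W, Wm)
}

.poolFwd <- function(X, H, W) {
  idx <- .getIdx(H, W)$pool
  a <- X[idx$i00, , drop = FALSE]; b <- X[idx$i10, , drop = FALSE]
  cc <- X[idx$i01, , drop = FALSE]; d <- X[idx$i11, , drop = FALSE]
  m1 <- pmax(a, b); m2 <- pmax(cc, d)
  list(Y = pmax(m1, m2), s1 = a >= b, s2 = cc >= d, sTop = m1 >= m2)
}

.poolBwd <- function(dY, pf, H, W) {
  idx <- .getIdx(H, W)$pool
  dX <- matrix(0, H * W, ncol(dY))
  top <- pf$sTop
  dX[idx$i00, ] <- dY * (top & pf$s1)
  dX[idx$i10, ] <- dY * (top & !pf$s1)
  dX[idx$i01, ] <- dX[idx$i01, ] + dY * (!top & pf$s2)
  dX[idx$i11, ] <- dX[idx$i11, ] + dY * (!top & !pf$s2)
  dX
}

.upFwd <- function(X, h, w) {
  X[.getIdx(2L * h, 2L * w)$up, , drop = FALSE]
}

.upBwd <- function(dY, h, w) {
  g <- .getIdx(2L * h, 2L * w)$up
  out <- rowsum(dY, g)
  dimnames(out) <- NULL
  out
}

## Weighted softmax cross-entropy.
## logits: HW x K; labels: integer vector in 0..K-1 (NA = ignore);
## weights: per-class loss weights. Returns loss and dLogits.
.softmaxLoss <- function(logits, labels, weights) {
  K <- ncol(logits)
  mx <- logits[, 1]
  for (k in 2:K) mx <- pmax(mx, logits[, k])
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  valid <- !is.na(labels)
  if (!any(valid)) return(list(loss = 0, dLogits = logits * 0, probs = p))
  li <- labels[valid] + 1L
  w <- weights[li]
  wsum <- sum(w)
  pv <- p[valid, , drop = FALSE]
  picked <- pv[cbind(seq_along(li), li)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / wsum
  dL <- matrix(0, nrow(logits), K)
  one <- matrix(0, length(li), K)
  one[cbind(seq_along(li), li)] <- 1
  dL[valid, ] <- (pv - one) * (w / wsum)
  list(loss = loss, dLogits = dL, probs = p)
}

.softmaxProbs <- function(logits) {
  mx <- logits[, 1]
  for (k in 2:ncol(logits)) mx <- pmax(mx, logits[, k])
  e <- exp(logits - mx)
  e / rowSums(e)
}

## Adam update; params/grads/state are flat named lists of numeric arrays.
.adamStep <- function(params, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / (1 - b1 ^ t)
    vhat <- state$v[[nm]] / (1 - b2 ^ t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.adamInit <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z)
}
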