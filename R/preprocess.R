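## Standardization chain: irregular raw records -> regular 1 s x 0.5 m grid
## -> 10-min x 500-m grayscale echograms.

.DB_FLOOR <- -90   # grayscale 0
.DB_CEIL  <- -20   # grayscale 1
.WIN_COLS <- 600L  # 10 min at 1 s
.WIN_ROWS <- 1000L # 500 m at 0.5 m

#' Regrid a raw acoustic record to the standard 1 s x 0.5 m grid
#'
#' Time is resampled to 1-s instants (t = 0, 1, 2, ... seconds since record
#' start); values at original ping instants are preserved and gaps longer
#' than 1 s are filled by linear interpolation of Sv in dB along time.
#' Depth is resampled by nearest-bin-center assignment to 0.5-m bins.
#' Missing samples (the reserved \code{NA} marker) are bridged by the same
#' temporal interpolation.
#'
#' @param record a \linkS4class{RawAcousticRecord} with at least 2 pings.
#' @param maxGapS gaps longer than this many seconds are left as missing
#'   instead of interpolated (default \code{Inf}: interpolate everything).
#' @param flagGapS columns inside ping gaps longer than this are flagged in
#'   the output's \code{gapFlagged} slot (default 10 s).
#' @return a \linkS4class{RegularSvMatrix}.
#' @examples
#' rec <- new("RawAcousticRecord",
#'            sv = matrix(c(-70, -60, -50), 1, 3),
#'            pingTimes = c(0, 2, 4), depthBins = 0.25,
#'            vesselId = "V", startTimestamp = Sys.time(), positions = NULL)
#' svMatrix(regridSv(rec))[1, 2]  # -65 dB at t = 1 s
#' @export
regridSv <- function(record, maxGapS = Inf, flagGapS = 10) {
  stopifnot(is(record, "RawAcousticRecord"))
  pt <- record@pingTimes
  if (length(pt) < 2)
    stop("regridSv needs at least 2 pings; got ", length(pt))
  if (any(diff(pt) <= 0)) stop("ping times must be strictly increasing")

  tout <- 0:floor(max(pt))                       # 1-s sample instants
  nT <- length(tout)

  ## nearest-bin-center depth assignment onto the 0.5-m grid
  db <- record@depthBins
  spacing <- if (length(db) > 1) stats::median(diff(db)) else 0.5
  maxDepth <- max(db) + spacing / 2
  nD <- max(1L, round(maxDepth / 0.5))
  centers <- seq(0.25, by = 0.5, length.out = nD)
  srcRow <- vapply(centers, function(d) which.min(abs(db - d)), integer(1))

  svIn <- record@sv[srcRow, , drop = FALSE]
  out <- matrix(NA_real_, nD, nT)
  for (r in seq_len(nD)) {
    v <- svIn[r, ]
    ok <- !is.na(v)
    if (sum(ok) >= 2) {
      out[r, ] <- stats::approx(pt[ok], v[ok], xout = tout,
                                method = "linear", rule = 1)$y
    } else if (sum(ok) == 1) {
      hit <- which(abs(outer(tout, pt[ok], "-")) < 1e-9, arr.ind = TRUE)
      if (nrow(hit)) out[r, hit[, 1]] <- v[ok][hit[, 2]]
    }
  }

  ## columns observed (coincide with a non-missing ping) vs interpolated
  validPing <- colSums(!is.na(record@sv)) > 0
  obsT <- pt[validPing]
  observed <- tout %in% round(obsT[abs(obsT - round(obsT)) < 1e-9])
  interpolated <- !observed & colSums(!is.na(out)) > 0

  ## gap bookkeeping on the valid-ping sequence
  gapFlag <- rep(FALSE, nT)
  if (length(obsT) >= 2) {
    gl <- diff(obsT)
    for (i in which(gl > flagGapS)) {
      inside <- tout > obsT[i] & tout < obsT[i + 1]
      gapFlag[inside] <- TRUE
    }
    if (is.finite(maxGapS)) {
      for (i in which(gl > maxGapS)) {
        inside <- tout > obsT[i] & tout < obsT[i + 1]
        out[, inside] <- NA_real_
      }
    }
  }

  new("RegularSvMatrix", sv = out, startTimestamp = record@startTimestamp,
      vesselId = record@vesselId, interpolated = interpolated,
      gapFlagged = gapFlag)
}

#' Convert Sv (dB) to grayscale in the fixed -90..-20 dB range
#'
#' Affine map with -90 dB -> 0 and -20 dB -> 1; values outside the range
#' are clipped to the nearest bound; missing values stay \code{NA}.
#'
#' @param x numeric vector/matrix of Sv in dB, or a
#'   \linkS4class{RegularSvMatrix}.
#' @return object of the same shape with grayscale values in [0, 1].
#' @examples
#' svToGrayscale(c(-90, -55, -20, -100))  # 0, 0.5, 1, 0
#' @export
svToGrayscale <- function(x) {
  if (is(x, "RegularSvMatrix")) x <- x@sv
  g <- (x - .DB_FLOOR) / (.DB_CEIL - .DB_FLOOR)
  g[g < 0] <- 0
  g[g > 1] <- 1
  g
}

#' Inverse of the grayscale map (for non-clipped pixels)
#' @param g grayscale values in [0, 1].
#' @return Sv in dB.
#' @export
grayscaleToSv <- function(g) .DB_FLOOR + g * (.DB_CEIL - .DB_FLOOR)

#' Split a regular Sv grid into standardized 10-min x 500-m echograms
#'
#' Consecutive non-overlapping 10-min (600-column) windows anchored at the
#' record start. Depth is truncated or padded to 500 m (1000 rows); a
#' trailing partial window is padded in time. Padding carries the reserved
#' \code{NA} marker and its fraction is recorded per window. Images are
#' converted to grayscale (see \code{\link{svToGrayscale}}).
#'
#' @param regular a \linkS4class{RegularSvMatrix}.
#' @param truth optional \linkS4class{GroundTruth} (or integer mask matrix)
#'   aligned to the same grid; windowed truth masks are attached to the
#'   echograms, with padding labelled background.
#' @return list of \linkS4class{Echogram} (empty for empty input).
#' @export
windowEchograms <- function(regular, truth = NULL) {
  stopifnot(is(regular, "RegularSvMatrix"))
  sv <- regular@sv
  nT <- ncol(sv); nD <- nrow(sv)
  if (nT == 0) return(list())
  tm <- NULL
  if (!is.null(truth)) {
    tm <- if (is(truth, "GroundTruth")) truth@mask else truth
    if (!identical(dim(tm), dim(sv)))
      stop("truth mask dimensions must match the regular grid")
  }
  nWin <- ceiling(nT / .WIN_COLS)
  rowsAvail <- min(nD, .WIN_ROWS)
  out <- vector("list", nWin)
  for (w in seq_len(nWin)) {
    c0 <- (w - 1L) * .WIN_COLS
    colsAvail <- min(.WIN_COLS, nT - c0)
    img <- matrix(NA_real_, .WIN_ROWS, .WIN_COLS)
    img[seq_len(rowsAvail), seq_len(colsAvail)] <-
      svToGrayscale(sv[seq_len(rowsAvail), c0 + seq_len(colsAvail),
                       drop = FALSE])
    nPad <- .WIN_ROWS * .WIN_COLS - rowsAvail * colsAvail
    tw <- matrix(integer(0), 0, 0)
    if (!is.null(tm)) {
      tw <- matrix(0L, .WIN_ROWS, .WIN_COLS)
      tw[seq_len(rowsAvail), seq_len(colsAvail)] <-
        tm[seq_len(rowsAvail), c0 + seq_len(colsAvail), drop = FALSE]
    }
    out[[w]] <- new("Echogram", image = img,
                    startTimestamp = regular@startTimestamp + c0,
                    vesselId = regular@vesselId,
                    fractionPadded = nPad / (.WIN_ROWS * .WIN_COLS),
                    truth = tw)
  }
  out
}
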