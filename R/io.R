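## File formats: long-form Sv CSV, PNG echograms and palette masks,
## tabular CSVs, and simple format conversion.

#' Write an Sv matrix to the documented long CSV format
#'
#' Columns: \code{time_s} (seconds since record start, column centre at
#' integer seconds for the regular grid), \code{depth_m} (bin centre),
#' \code{sv_db}. Missing samples are written as empty fields.
#'
#' @param x a \linkS4class{RegularSvMatrix} or \linkS4class{RawAcousticRecord}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSvCsv <- function(x, path) {
  if (is(x, "RegularSvMatrix")) {
    times <- seq_len(ncol(x@sv)) - 1
    depths <- seq(0.25, by = 0.5, length.out = nrow(x@sv))
    sv <- x@sv
  } else if (is(x, "RawAcousticRecord")) {
    times <- x@pingTimes
    depths <- x@depthBins
    sv <- x@sv
  } else stop("unsupported object for Sv CSV export")
  df <- data.frame(time_s = rep(times, each = length(depths)),
                   depth_m = rep(depths, length(times)),
                   sv_db = as.vector(sv))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the long Sv CSV format back into a raw record
#'
#' @param path CSV written by \code{\link{writeSvCsv}}.
#' @param vesselId,startTimestamp metadata for the reconstructed record.
#' @return a \linkS4class{RawAcousticRecord}.
#' @export
readSvCsv <- function(path, vesselId = "CSV",
                      startTimestamp = as.POSIXct("2022-01-15 00:00:00",
                                                  tz = "UTC")) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "depth_m", "sv_db") %in% names(df)))
  times <- sort(unique(df$time_s))
  depths <- sort(unique(df$depth_m))
  sv <- matrix(NA_real_, length(depths), length(times))
  sv[cbind(match(df$depth_m, depths), match(df$time_s, times))] <- df$sv_db
  new("RawAcousticRecord", sv = sv, pingTimes = times, depthBins = depths,
      vesselId = vesselId, startTimestamp = startTimestamp,
      positions = NULL)
}

#' Write an echogram as a grayscale PNG (padding as alpha)
#'
#' @param echogram an \linkS4class{Echogram} or grayscale matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeEchogramPng <- function(echogram, path) {
  img <- if (is(echogram, "Echogram")) echogram@image else echogram
  a <- array(0, c(nrow(img), ncol(img), 2))
  g <- img
  pad <- is.na(g)
  g[pad] <- 0
  a[, , 1] <- g
  a[, , 2] <- 1 - pad        # alpha: 0 where padded
  png::writePNG(a, path)
  invisible(path)
}

#' Read a grayscale PNG echogram back to a matrix
#'
#' Grayscale is quantized to 8 or 16 bits by the PNG format; fully
#' transparent pixels are restored as \code{NA} padding.
#'
#' @param path PNG written by \code{\link{writeEchogramPng}}.
#' @return numeric matrix in [0,1] with NA padding.
#' @export
readEchogramPng <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) return(a)
  g <- a[, , 1]
  if (dim(a)[3] %in% c(2, 4)) {
    alpha <- a[, , dim(a)[3]]
    g[alpha == 0] <- NA_real_
  }
  g
}

.maskPalette <- c("#000000", "#8B5A2B", "#1B9E77", "#D95F02", "#7570B3")

#' Write a palette-coded class mask as PNG
#' @param mask SegmentationMask, GroundTruth or integer matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPng <- function(mask, path) {
  m <- if (is(mask, "SegmentationMask")) mask@labels else
       if (is(mask, "GroundTruth")) mask@mask else mask
  cols <- grDevices::col2rgb(.maskPalette) / 255
  a <- array(0, c(nrow(m), ncol(m), 3))
  for (k in 0:4) {
    sel <- m == k
    for (ch in 1:3) {
      plane <- a[, , ch]
      plane[sel] <- cols[ch, k + 1]
      a[, , ch] <- plane
    }
  }
  png::writePNG(a, path)
  invisible(path)
}

#' Read a palette-coded mask PNG back to class codes
#' @param path PNG written by \code{\link{writeMaskPng}}.
#' @return integer matrix of class codes.
#' @export
readMaskPng <- function(path) {
  a <- png::readPNG(path)
  cols <- grDevices::col2rgb(.maskPalette) / 255
  H <- dim(a)[1]; W <- dim(a)[2]
  flat <- matrix(aperm(a[, , 1:3], c(3, 1, 2)), nrow = 3)
  d <- vapply(1:5, function(k)
    colSums((flat - cols[, k]) ^ 2), numeric(ncol(flat)))
  matrix(as.integer(max.col(-d) - 1L), H, W)
}

#' Write dive events to CSV (ISO-8601 timestamps, WGS84 coordinates)
#' @param events DiveEvent data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEventsCsv <- function(events, path) {
  ev <- events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Convert between supported acoustic file formats
#'
#' Supported conversions: \code{"csv"} (long-form Sv) to/from
#' \code{"png"} (grayscale echogram of the regridded data). Conversion to
#' PNG quantizes grayscale to the PNG bit depth.
#'
#' @param path input file.
#' @param from,to format names.
#' @param out output file path.
#' @return the output path, invisibly.
#' @export
convertFormats <- function(path, from, to, out) {
  pair <- paste(from, to, sep = "->")
  if (pair == "csv->png") {
    rec <- readSvCsv(path)
    reg <- regridSv(rec)
    writeEchogramPng(svToGrayscale(reg), out)
  } else if (pair == "png->csv") {
    g <- readEchogramPng(path)
    sv <- grayscaleToSv(g)
    reg <- new("RegularSvMatrix", sv = sv,
               startTimestamp = as.POSIXct("2022-01-15 00:00:00",
                                           tz = "UTC"),
               vesselId = "PNG",
               interpolated = rep(FALSE, ncol(sv)),
               gapFlagged = rep(FALSE, ncol(sv)))
    writeSvCsv(reg, out)
  } else {
    stop("unsupported conversion '", pair,
         "'; supported: csv->png, png->csv")
  }
  invisible(out)
}
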