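#' Extract the Sv (or grayscale) matrix from an acoustics object
#' @param x an object holding a time x depth matrix
#' @return numeric matrix, rows = depth bins, columns = time.
#' @export
setGeneric("svMatrix", function(x) standardGeneric("svMatrix"))

#' @describeIn svMatrix Sv matrix of a raw record (dB)
#' @export
setMethod("svMatrix", "RawAcousticRecord", function(x) x@sv)

#' @describeIn svMatrix Sv matrix of a regular grid (dB)
#' @export
setMethod("svMatrix", "RegularSvMatrix", function(x) x@sv)

#' Ping times of a raw record (seconds since record start)
#' @param x a RawAcousticRecord
#' @return numeric vector of ping times.
#' @export
setGeneric("pingTimes", function(x) standardGeneric("pingTimes"))

#' @rdname pingTimes
#' @export
setMethod("pingTimes", "RawAcousticRecord", function(x) x@pingTimes)

#' Depth bin centers (metres)
#' @param x a RawAcousticRecord
#' @return numeric vector of depth bin centers.
#' @export
setGeneric("depthBins", function(x) standardGeneric("depthBins"))

#' @rdname depthBins
#' @export
setMethod("depthBins", "RawAcousticRecord", function(x) x@depthBins)

#' Vessel identifier
#' @param x an acoustics object carrying vessel metadata
#' @return character scalar.
#' @export
setGeneric("vesselId", function(x) standardGeneric("vesselId"))

#' @rdname vesselId
#' @export
setMethod("vesselId", "RawAcousticRecord", function(x) x@vesselId)

#' @rdname vesselId
#' @export
setMethod("vesselId", "RegularSvMatrix", function(x) x@vesselId)

#' @rdname vesselId
#' @export
setMethod("vesselId", "Echogram", function(x) x@vesselId)

#' Grayscale image of an echogram
#' @param x an Echogram
#' @return numeric 1000 x 600 matrix in [0,1], NA = padding.
#' @export
setGeneric("echogramImage", function(x) standardGeneric("echogramImage"))

#' @rdname echogramImage
#' @export
setMethod("echogramImage", "Echogram", function(x) x@image)

#' Fraction of padded (unobserved) pixels in an echogram
#' @param x an Echogram
#' @return numeric in [0,1].
#' @export
setGeneric("fractionPadded", function(x) standardGeneric("fractionPadded"))

#' @rdname fractionPadded
#' @export
setMethod("fractionPadded", "Echogram", function(x) x@fractionPadded)

#' Label / truth mask matrix
#' @param x a SegmentationMask, GroundTruth or Echogram
#' @return integer matrix of class codes (see \code{\link{classCodes}});
#'   for an Echogram without attached truth, a 0 x 0 matrix.
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "SegmentationMask", function(x) x@labels)

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "GroundTruth", function(x) x@mask)

#' @rdname maskMatrix
#' @export
setMethod("maskMatrix", "Echogram", function(x) x@truth)

#' Planted event table of a synthetic scene
#' @param x a GroundTruth
#' @return data.frame of planted predator events.
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname truthEvents
#' @export
setMethod("truthEvents", "GroundTruth", function(x) x@events)

#' Probability array of a ProbabilityMap
#' @param x a ProbabilityMap
#' @return rows x cols x 5 numeric array.
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))

#' @rdname probArray
#' @export
setMethod("probArray", "ProbabilityMap", function(x) x@probs)

#' Training history of a UNetModel
#' @param x a UNetModel
#' @return data.frame with per-epoch losses (empty if untrained).
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "UNetModel", function(x) x@history)

#' Trainable parameter count of a UNetModel
#' @param x a UNetModel
#' @return integer.
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' @rdname nParameters
#' @export
setMethod("nParameters", "UNetModel", function(x) x@nParams)

setMethod("show", "RawAcousticRecord", function(object) {
  cat("RawAcousticRecord:", length(object@pingTimes), "pings x",
      length(object@depthBins), "depth bins\n")
  cat("  vessel:", object@vesselId,
      " start:", format(object@startTimestamp, "%Y-%m-%d %H:%M:%S UTC"), "\n")
  cat("  time span:", round(diff(range(object@pingTimes)), 1), "s;",
      "depth:", min(object@depthBins), "-", max(object@depthBins), "m\n")
  cat("  missing samples:", sum(is.na(object@sv)), "\n")
})

setMethod("show", "RegularSvMatrix", function(object) {
  cat("RegularSvMatrix:", nrow(object@sv), "x", ncol(object@sv),
      "(0.5 m depth x 1 s time)\n")
  cat("  vessel:", object@vesselId, "; interpolated columns:",
      sum(object@interpolated), "; flagged gap columns:",
      sum(object@gapFlagged), "\n")
})

setMethod("show", "Echogram", function(object) {
  cat("Echogram 1000 x 600 (500 m x 10 min), vessel:", object@vesselId, "\n")
  cat("  start:", format(object@startTimestamp, "%Y-%m-%d %H:%M:%S UTC"),
      "; padded fraction:", round(object@fractionPadded, 3),
      "; truth:", if (length(object@truth)) "attached" else "none", "\n")
})

setMethod("show", "GroundTruth", function(object) {
  tab <- table(factor(object@mask, levels = unname(classCodes()),
                      labels = classNames()))
  cat("GroundTruth mask", nrow(object@mask), "x", ncol(object@mask),
      "with", nrow(object@events), "planted predator events\n")
  print(round(100 * tab / length(object@mask), 2))
})

setMethod("show", "SegmentationMask", function(object) {
  cat("SegmentationMask", nrow(object@labels), "x", ncol(object@labels),
      "(", object@provenance, ")\n")
  cnt <- table(factor(object@labels, levels = unname(classCodes()),
                      labels = classNames()))
  print(cnt)
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat("UNetModel:", cfg$levels, "levels, base", cfg$baseFilters,
      "filters, bridge", cfg$bridgeWidth, ",", cfg$nClasses, "classes\n")
  cat("  tile", cfg$tileSize, "x", cfg$tileSize, ";",
      object@nParams, "trainable parameters;",
      if (nrow(object@history)) paste("trained", nrow(object@history),
                                      "epochs") else "untrained", "\n")
})
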