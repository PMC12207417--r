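#' @import methods
NULL

## Class codes used in every mask in the package. Pixel value = code.
## Order encodes nothing; precedence for overlap resolution is separate.

#' Segmentation class table
#'
#' The five pixel classes used throughout the package, with their integer
#' mask codes: background = 0, seafloor = 1, krill_swarm = 2, whale = 3,
#' bubble_trail = 4.
#'
#' @return Named integer vector mapping class name to mask code.
#' @examples
#' classCodes()
#' @export
classCodes <- function() {
  c(background = 0L, seafloor = 1L, krill_swarm = 2L,
    whale = 3L, bubble_trail = 4L)
}

#' Class names in mask-code order
#' @return Character vector of the five class names, index = code + 1.
#' @export
classNames <- function() names(classCodes())

## Overlap precedence when planting / tie-breaking when thresholding:
## stronger scatterers (and the rare, loss-up-weighted classes) win.
.classPrecedence <- c(whale = 5L, bubble_trail = 4L, krill_swarm = 3L,
                      seafloor = 2L, background = 1L)

.PAD <- NA_real_   # reserved missing / padding marker for Sv and grayscale

#' RawAcousticRecord: irregular echosounder pings
#'
#' Volume backscattering strength Sv (dB re 1 m-1) sampled at possibly
#' irregular ping times over a regular depth axis. Missing samples carry
#' \code{NA}, never silently dropped.
#'
#' @slot sv numeric matrix, rows = depth bins, columns = pings, in dB.
#' @slot pingTimes numeric, seconds since record start, strictly increasing.
#' @slot depthBins numeric, depth bin centers in metres, regular, increasing.
#' @slot vesselId character scalar.
#' @slot startTimestamp POSIXct, UTC time of the first ping.
#' @slot positions \code{NULL} or data.frame with per-ping \code{lat}, \code{lon}.
#' @export
setClass("RawAcousticRecord",
  representation(sv = "matrix", pingTimes = "numeric", depthBins = "numeric",
                 vesselId = "character", startTimestamp = "POSIXct",
                 positions = "ANY"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@sv) != length(object@pingTimes))
      msg <- c(msg, "ncol(sv) must equal length(pingTimes)")
    if (nrow(object@sv) != length(object@depthBins))
      msg <- c(msg, "nrow(sv) must equal length(depthBins)")
    if (length(object@pingTimes) > 1 && any(diff(object@pingTimes) <= 0))
      msg <- c(msg, "pingTimes must be strictly increasing")
    if (length(object@depthBins) > 1 && any(diff(object@depthBins) <= 0))
      msg <- c(msg, "depthBins must be increasing")
    if (length(msg)) msg else TRUE
  })

#' RegularSvMatrix: Sv on the standard 1 s x 0.5 m grid
#'
#' @slot sv numeric matrix (dB), rows = 0.5-m depth bins from the
#'   transducer, columns = 1-s time steps.
#' @slot startTimestamp POSIXct of the first column.
#' @slot vesselId character scalar.
#' @slot interpolated logical per column: TRUE where the column was filled
#'   by temporal interpolation rather than observed.
#' @slot gapFlagged logical per column: TRUE where the column lies inside a
#'   ping gap longer than the max-gap setting of \code{\link{regridSv}}.
#' @export
setClass("RegularSvMatrix",
  representation(sv = "matrix", startTimestamp = "POSIXct",
                 vesselId = "character", interpolated = "logical",
                 gapFlagged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@interpolated) != ncol(object@sv))
      msg <- c(msg, "interpolated must have one entry per time column")
    if (length(object@gapFlagged) != ncol(object@sv))
      msg <- c(msg, "gapFlagged must have one entry per time column")
    if (length(msg)) msg else TRUE
  })

#' Echogram: standardized 600 x 1000 grayscale window
#'
#' One 10-min x 500-m analysis window. The image is grayscale in [0, 1]
#' (affine map of Sv from -90 dB -> 0 to -20 dB -> 1, clipped); padding
#' introduced to reach the standard extent carries \code{NA} so it can never
#' masquerade as quiet water.
#'
#' @slot image numeric matrix 1000 rows (depth, 0.5 m) x 600 columns
#'   (time, 1 s); values in [0,1] or NA (padding).
#' @slot startTimestamp POSIXct of column 1.
#' @slot vesselId character scalar.
#' @slot fractionPadded numeric in [0,1]: fraction of pixels that are
#'   padding (not observed data).
#' @slot truth integer matrix of the same shape with mask codes, or a
#'   0 x 0 matrix when no ground truth is attached.
#' @export
setClass("Echogram",
  representation(image = "matrix", startTimestamp = "POSIXct",
                 vesselId = "character", fractionPadded = "numeric",
                 truth = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@image), c(1000L, 600L)))
      msg <- c(msg, "image must be exactly 1000 rows x 600 columns")
    v <- object@image[!is.na(object@image)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "grayscale values must lie in [0, 1]")
    if (object@fractionPadded < 0 || object@fractionPadded > 1)
      msg <- c(msg, "fractionPadded must lie in [0, 1]")
    if (length(object@truth) && !identical(dim(object@truth), dim(object@image)))
      msg <- c(msg, "truth mask must match image dimensions")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: pixel mask plus planted event table
#'
#' Truth for a synthetic scene on the 1 s x 0.5 m grid. Mask codes follow
#' \code{\link{classCodes}}. The event table holds one row per planted
#' predator object (whale dives and bubble trails).
#'
#' @slot mask integer matrix, rows = depth, columns = time (1 s).
#' @slot events data.frame with columns event_id, object_class, start_s,
#'   end_s, depth_top_m, depth_bottom_m, duration_s, height_m.
#' @export
setClass("GroundTruth",
  representation(mask = "matrix", events = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@mask) &&
        !all(object@mask %in% unname(classCodes())))
      msg <- c(msg, "mask values must be valid class codes 0..4")
    need <- c("event_id", "object_class", "start_s", "end_s",
              "depth_top_m", "depth_bottom_m", "duration_s", "height_m")
    if (nrow(object@events) && !all(need %in% names(object@events)))
      msg <- c(msg, "events table is missing required columns")
    if (length(msg)) msg else TRUE
  })

#' SegmentationMask: per-pixel class labels
#'
#' @slot labels integer matrix of mask codes (see \code{\link{classCodes}}).
#' @slot provenance one of "model", "reference", "truth".
#' @export
setClass("SegmentationMask",
  representation(labels = "matrix", provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(object@labels %in% unname(classCodes())))
      msg <- c(msg, "labels must be valid class codes 0..4")
    if (!object@provenance %in% c("model", "reference", "truth"))
      msg <- c(msg, "provenance must be model, reference or truth")
    if (length(msg)) msg else TRUE
  })

#' ProbabilityMap: per-pixel class probabilities
#'
#' @slot probs numeric array rows x cols x 5; each pixel's probabilities are
#'   nonnegative and sum to 1 (within 1e-6).
#' @export
setClass("ProbabilityMap",
  representation(probs = "array"),
  validity = function(object) {
    d <- dim(object@probs)
    if (length(d) != 3 || d[3] != length(classCodes()))
      return("probs must be a rows x cols x 5 array")
    s <- apply(object@probs, c(1, 2), sum)
    if (any(abs(s - 1) > 1e-6) || any(object@probs < -1e-12))
      return("per-pixel probabilities must be nonnegative and sum to 1")
    TRUE
  })

#' UNetModel: a (possibly trained) segmentation network
#'
#' @slot config list, see \code{\link{unetConfig}}.
#' @slot params list of layer weights.
#' @slot history data.frame of per-epoch train/validation loss (empty until
#'   trained).
#' @slot nParams integer, trainable parameter count.
#' @export
setClass("UNetModel",
  representation(config = "ANY", params = "list", history = "data.frame",
                 nParams = "integer"))
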