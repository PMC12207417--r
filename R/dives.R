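## From segmentation masks to discrete dive events.

#' Extract predator polygons from a segmentation mask
#'
#' Finds 8-connected components of the two predator classes (whale,
#' bubble_trail) separately, drops components smaller than
#' \code{minPixels}, and returns them ordered by (colMin, rowMin).
#' 8-connectivity is essential for bubble trails, whose thin diagonal
#' streaks would shatter under 4-connectivity.
#'
#' @param mask a \linkS4class{SegmentationMask} or integer matrix.
#' @param minPixels minimum component size (default 6, suppressing
#'   single-pixel noise).
#' @param echogramId identifier copied onto each polygon.
#' @return data.frame with one row per polygon: \code{polygon_id},
#'   \code{object_class}, \code{col_min}, \code{col_max}, \code{row_min},
#'   \code{row_max}, \code{n_pixels}, \code{echogram_id}, plus a
#'   list-column \code{pixels} of 2-column (row, col) matrices.
#' @export
extractDivePolygons <- function(mask, minPixels = 6, echogramId = "") {
  m <- if (is(mask, "SegmentationMask")) mask@labels else
       if (is(mask, "GroundTruth")) mask@mask else mask
  H <- nrow(m)
  rows <- list()
  for (code in c(3L, 4L)) {
    lab <- .labelComponents(m == code)
    if (max(lab) == 0) next
    pix <- which(lab > 0)
    comp <- lab[pix]
    pr <- ((pix - 1L) %% H) + 1L
    pc <- ((pix - 1L) %/% H) + 1L
    for (id in seq_len(max(lab))) {
      sel <- comp == id
      if (sum(sel) < minPixels) next
      rows[[length(rows) + 1L]] <- data.frame(
        object_class = classNames()[code + 1L],
        col_min = min(pc[sel]), col_max = max(pc[sel]),
        row_min = min(pr[sel]), row_max = max(pr[sel]),
        n_pixels = sum(sel), echogram_id = echogramId,
        pixels = I(list(cbind(row = pr[sel], col = pc[sel]))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(polygon_id = integer(0), object_class = character(0),
                      col_min = integer(0), col_max = integer(0),
                      row_min = integer(0), row_max = integer(0),
                      n_pixels = integer(0), echogram_id = character(0),
                      pixels = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$col_min, out$row_min), , drop = FALSE]
  out <- cbind(polygon_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Classify a mammal dive by acoustic height
#'
#' Antarctic fur seals (body length around 2 m) can only produce signals up
#' to about 2 m high, while baleen whale bodies are 3 m or more in
#' diameter; the band between 2 and 3 m is ambiguous.
#'
#' @param heightM acoustic height(s) in metres, > 0.
#' @return character vector: "seal_like" (< 2 m), "ambiguous" (2 to < 3 m)
#'   or "whale_like" (>= 3 m).
#' @examples
#' classifyMammalDive(c(1.5, 2.5, 10))
#' @export
classifyMammalDive <- function(heightM) {
  if (any(heightM <= 0)) stop("acoustic height must be positive")
  ifelse(heightM < 2, "seal_like",
         ifelse(heightM < 3, "ambiguous", "whale_like"))
}

#' Measure dive polygons into dive events
#'
#' Durations use the inclusive pixel span at 1 pixel = 1 s; acoustic
#' heights use the inclusive row span at 1 pixel = 0.5 m, so a single-pixel
#' polygon measures 1 s x 0.5 m. Event timestamps are the window start plus
#' the first column's offset; positions are linearly interpolated from the
#' vessel track at the event timestamp (left empty when no track covers
#' it). Whale-class events get a taxon group from
#' \code{\link{classifyMammalDive}}; bubble trails are reported without a
#' taxon split.
#'
#' @param polygons data.frame from \code{\link{extractDivePolygons}}.
#' @param windowStart POSIXct start of the source echogram window.
#' @param track optional VesselTrack data.frame (columns timestamp, lat,
#'   lon).
#' @param windowCols number of time columns in the window (600); events
#'   touching the window boundary are flagged.
#' @return data.frame of DiveEvents: \code{event_id}, \code{object_class},
#'   \code{taxon_group}, \code{duration_s}, \code{duration_min},
#'   \code{acoustic_height_m}, \code{timestamp}, \code{lat}, \code{lon},
#'   \code{window_boundary}, \code{qc_flag}, \code{echogram_id}.
#' @export
measureDives <- function(polygons, windowStart, track = NULL,
                         windowCols = 600L) {
  n <- nrow(polygons)
  if (n == 0)
    return(data.frame(event_id = character(0), object_class = character(0),
                      taxon_group = character(0), duration_s = numeric(0),
                      duration_min = numeric(0),
                      acoustic_height_m = numeric(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      lat = numeric(0), lon = numeric(0),
                      window_boundary = logical(0), qc_flag = character(0),
                      echogram_id = character(0), stringsAsFactors = FALSE))
  durS <- polygons$col_max - polygons$col_min + 1
  hM <- (polygons$row_max - polygons$row_min + 1) * 0.5
  ts <- windowStart + (polygons$col_min - 1)
  lat <- rep(NA_real_, n); lon <- rep(NA_real_, n)
  if (!is.null(track) && nrow(track) >= 2) {
    tt <- as.numeric(track$timestamp)
    te <- as.numeric(ts)
    cover <- te >= min(tt) & te <= max(tt)
    if (any(cover)) {
      lat[cover] <- stats::approx(tt, track$lat, xout = te[cover])$y
      lon[cover] <- stats::approx(tt, track$lon, xout = te[cover])$y
    }
  }
  taxon <- ifelse(polygons$object_class == "whale",
                  classifyMammalDive(hM), "unclassified")
  data.frame(
    event_id = sprintf("%s_ev%03d", polygons$echogram_id,
                       polygons$polygon_id),
    object_class = polygons$object_class,
    taxon_group = taxon,
    duration_s = durS, duration_min = durS / 60,
    acoustic_height_m = hM,
    timestamp = ts, lat = lat, lon = lon,
    window_boundary = polygons$col_min == 1 |
      polygons$col_max == windowCols,
    qc_flag = "kept", echogram_id = polygons$echogram_id,
    stringsAsFactors = FALSE)
}

#' Histogram of acoustic heights of dive events
#'
#' @param events DiveEvent data.frame.
#' @param binM bin width in metres (> 0); bins are half-open
#'   \code{[k*binM, (k+1)*binM)}.
#' @return data.frame with columns \code{height_lo_m}, \code{height_hi_m},
#'   \code{count}; counts sum to \code{nrow(events)}.
#' @export
acousticHeightHistogram <- function(events, binM = 1) {
  if (binM <= 0) stop("binM must be > 0")
  if (!nrow(events))
    return(data.frame(height_lo_m = numeric(0), height_hi_m = numeric(0),
                      count = integer(0)))
  b <- floor(events$acoustic_height_m / binM)
  tab <- table(b)
  data.frame(height_lo_m = as.numeric(names(tab)) * binM,
             height_hi_m = (as.numeric(names(tab)) + 1) * binM,
             count = as.integer(tab))
}

#' Apply manual quality-control flags to dive events
#'
#' Mirrors the manual false-positive removal step: every detection gets a
#' control plot for inspection, and a flag table marks events to remove.
#' Removed events stay in the returned table with \code{qc_flag =
#' "removed"} but are excluded from all downstream encounter rates (which
#' only consume kept events).
#'
#' @param events DiveEvent data.frame.
#' @param flags data.frame with columns \code{event_id} and \code{keep}
#'   (logical) or \code{action} ("keep"/"remove"). An empty table keeps
#'   everything.
#' @param controlPlotDir optional directory; when given, one PNG control
#'   plot per event is written (requires \code{echograms}).
#' @param echograms optional named list of \linkS4class{Echogram} objects
#'   (names = echogram ids) used for control plots.
#' @return the events table with updated \code{qc_flag}.
#' @export
applyQc <- function(events, flags = NULL, controlPlotDir = NULL,
                    echograms = NULL) {
  if (!is.null(flags) && nrow(flags)) {
    unknown <- setdiff(flags$event_id, events$event_id)
    if (length(unknown))
      stop("QC flags reference unknown event ids: ",
           paste(unknown, collapse = ", "))
    rm <- if ("keep" %in% names(flags)) flags$event_id[!flags$keep]
          else flags$event_id[flags$action == "remove"]
    events$qc_flag[events$event_id %in% rm] <- "removed"
  }
  if (!is.null(controlPlotDir) && !is.null(echograms) && nrow(events)) {
    dir.create(controlPlotDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(events))) {
      eg <- echograms[[events$echogram_id[i]]]
      if (is.null(eg)) next
      f <- file.path(controlPlotDir,
                     paste0(events$event_id[i], ".png"))
      img <- echogramImage(eg)
      img[is.na(img)] <- 0
      grDevices::png(f, width = 600, height = 400)
      graphics::par(mar = c(2, 2, 2, 1))
      graphics::image(t(img[rev(seq_len(nrow(img))), ]),
                      col = grDevices::gray.colors(64, 0, 1),
                      main = paste(events$event_id[i],
                                   events$object_class[i]))
      grDevices::dev.off()
    }
  }
  events
}

#' Keep only events that passed quality control
#' @param events DiveEvent data.frame.
#' @return the subset with \code{qc_flag == "kept"}.
#' @export
keptEvents <- function(events) events[events$qc_flag == "kept", ,
                                      drop = FALSE]
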