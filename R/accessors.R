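# Accessors and show methods for the core classes.

#' @describeIn Movie-classes list of frames.
#' @param x a movie object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @export
setMethod("frames", "PhaseMovie", function(x) x@frames)
#' @export
setMethod("frames", "FluorMovie", function(x) x@frames)

#' @describeIn Movie-classes number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "PhaseMovie", function(x) length(x@frames))
#' @export
setMethod("nFrames", "FluorMovie", function(x) length(x@frames))

#' @describeIn Movie-classes (rows, cols) of each frame.
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @export
setMethod("frameDim", "PhaseMovie", function(x) dim(x@frames[[1L]]))
#' @export
setMethod("frameDim", "FluorMovie", function(x) dim(x@frames[[1L]]))

#' @describeIn Movie-classes extract frame `i` as a matrix.
#' @param i frame index.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @export
setMethod("getFrame", "PhaseMovie", function(x, i) x@frames[[i]])
#' @export
setMethod("getFrame", "FluorMovie", function(x, i) x@frames[[i]])

setMethod("show", "PhaseMovie", function(object) {
  d <- frameDim(object)
  cat(sprintf("PhaseMovie: %d frame(s) of %dx%d (8-bit)\n",
              nFrames(object), d[1L], d[2L]))
})

setMethod("show", "FluorMovie", function(object) {
  d <- frameDim(object)
  cat(sprintf("FluorMovie '%s': %d frame(s) of %dx%d\n",
              object@channelName, nFrames(object), d[1L], d[2L]))
})

#' @describeIn SeedLabelImage-class the raw integer label matrix.
#' @param x a `SeedLabelImage`.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @export
setMethod("labelMatrix", "SeedLabelImage", function(x) x@labels)

#' @describeIn SeedLabelImage-class number of distinct cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setMethod("nCells", "SeedLabelImage", function(x)
  length(setdiff(unique(as.vector(x@labels)), 0L)))

#' @export
setMethod("nCells", "TrackingResult", function(x) length(x@tracks))

setMethod("show", "SeedLabelImage", function(object) {
  cat(sprintf("SeedLabelImage: %dx%d, %d cell(s)\n",
              nrow(object@labels), ncol(object@labels), nCells(object)))
})

#' @describeIn CompositeScore-class the score matrix.
#' @param x a `CompositeScore`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setMethod("scores", "CompositeScore", function(x) x@scores)

#' @describeIn CompositeScore-class the processing stage.
#' @export
setGeneric("scoreStage", function(x) standardGeneric("scoreStage"))

#' @export
setMethod("scoreStage", "CompositeScore", function(x) x@stage)

setMethod("show", "CompositeScore", function(object) {
  cat(sprintf("CompositeScore (%s): %dx%d, range [%.2f, %.2f]\n",
              object@stage, nrow(object@scores), ncol(object@scores),
              min(object@scores), max(object@scores)))
})

#' @describeIn CellTrack-class seed label id of the tracked cell.
#' @param x a `CellTrack`.
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @export
setMethod("cellId", "CellTrack", function(x) x@cellId)

#' @describeIn CellTrack-class segmented frame indices (descending).
#' @export
setGeneric("trackFrames", function(x) standardGeneric("trackFrames"))

#' @export
setMethod("trackFrames", "CellTrack", function(x) x@frames)

#' @describeIn CellTrack-class first backward frame not segmented (or NULL).
#' @export
setGeneric("disappearanceFrame", function(x) standardGeneric("disappearanceFrame"))

#' @export
setMethod("disappearanceFrame", "CellTrack", function(x) x@disappearanceFrame)

#' @describeIn CellTrack-class why the track stopped.
#' @export
setGeneric("terminationReason", function(x) standardGeneric("terminationReason"))

#' @export
setMethod("terminationReason", "CellTrack", function(x) x@terminationReason)

#' Reconstruct a cell's mask at one frame
#'
#' @param track a [CellTrack-class].
#' @param frame frame index.
#' @return A logical full-frame matrix; an all-`FALSE` matrix if the cell was
#'   not segmented at `frame`.
#' @export
maskAt <- function(track, frame) {
  m <- matrix(FALSE, track@frameDim[1L], track@frameDim[2L])
  k <- match(frame, track@frames)
  if (!is.na(k)) m[track@maskIdx[[k]]] <- TRUE
  m
}

setMethod("show", "CellTrack", function(object) {
  cat(sprintf("CellTrack %d: %d frame(s)", object@cellId,
              length(object@frames)))
  if (length(object@frames))
    cat(sprintf(" [%d..%d]", object@frames[1L],
                object@frames[length(object@frames)]))
  cat(sprintf(", termination: %s", object@terminationReason))
  if (!is.null(object@disappearanceFrame))
    cat(sprintf(" at frame %d", object@disappearanceFrame))
  cat("\n")
})

#' @describeIn TrackingResult-class list of per-cell tracks.
#' @param x a `TrackingResult`.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @export
setMethod("tracks", "TrackingResult", function(x) x@tracks)

#' @describeIn TrackingResult-class configuration used for the run.
#' @export
setGeneric("configUsed", function(x) standardGeneric("configUsed"))

#' @export
setMethod("configUsed", "TrackingResult", function(x) x@config)

#' @describeIn TrackingResult-class event log data.frame.
#' @export
setGeneric("trackingLog", function(x) standardGeneric("trackingLog"))

#' @export
setMethod("trackingLog", "TrackingResult", function(x) x@log)

setMethod("show", "TrackingResult", function(object) {
  n <- length(object@tracks)
  nf <- vapply(object@tracks, function(t) length(t@frames), integer(1))
  cat(sprintf("TrackingResult: %d cell(s), %d segmentations\n", n, sum(nf)))
  reasons <- vapply(object@tracks, terminationReason, character(1))
  for (r in unique(reasons))
    cat(sprintf("  %s: %d\n", r, sum(reasons == r)))
})

setMethod("show", "TrackConfig", function(object) {
  cat("TrackConfig:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %s = %g\n", nm, slot(object, nm)))
})

setMethod("show", "ColonyParams", function(object) {
  cat(sprintf("ColonyParams: %d founder(s), %d frame(s), %dx%d\n",
              as.integer(object@nInitialCells), as.integer(object@nFrames),
              as.integer(object@frameShape[1L]),
              as.integer(object@frameShape[2L])))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frame(s), %d cell(s) (%d bud(s))\n",
              length(object@labelMovie), nrow(object@lineage),
              sum(!is.na(object@lineage$motherId))))
})

#' @describeIn GroundTruth-class list of per-frame label matrices.
#' @param x a `GroundTruth`.
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @export
setMethod("truthLabels", "GroundTruth", function(x) x@labelMovie)

#' @describeIn GroundTruth-class lineage table (id, birthFrame, motherId).
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))

#' @export
setMethod("lineage", "GroundTruth", function(x) x@lineage)

setMethod("show", "TrackingSummary", function(object) {
  cat("TrackingSummary:\n")
  cat(sprintf("  cells: %d, segmentations: %d\n", object@nCells,
              object@nSegmentations))
  cat(sprintf("  proper: %.1f%%  minor: %.1f%%  major: %.1f%%\n",
              100 * object@fractionProper, 100 * object@fractionMinor,
              100 * object@fractionMajor))
  cat(sprintf("  error-free tracks: %.1f%%\n",
              100 * object@fractionErrorFreeTracks))
})
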