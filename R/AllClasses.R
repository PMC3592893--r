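#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Movie containers
#'
#' `PhaseMovie` holds an ordered stack of 8-bit phase-contrast frames
#' (integer matrices with values in 0--255); `FluorMovie` holds a
#' co-registered fluorescence channel at native depth (non-negative real
#' matrices).  Frames are stored in acquisition order; the tracker iterates
#' an explicit descending frame index, so "first segmented time point" means
#' the highest frame index of interest.
#'
#' @slot frames list of 2D matrices, all of identical dimensions.
#' @slot frameInterval minutes between frames (metadata only).
#' @slot pixelSize micrometers per pixel (metadata, may be `NA`).
#' @slot channelName fluorescence channel label.
#'
#' @aliases PhaseMovie-class FluorMovie-class
#' @name Movie-classes
#' @rdname Movie-classes
#' @exportClass PhaseMovie
setClass("PhaseMovie",
  representation(frames = "list", frameInterval = "numeric",
                 pixelSize = "numeric"),
  prototype(frames = list(), frameInterval = NA_real_, pixelSize = NA_real_))

#' @rdname Movie-classes
#' @exportClass FluorMovie
setClass("FluorMovie",
  representation(frames = "list", channelName = "character"),
  prototype(frames = list(), channelName = "fluor"))

.validMovieFrames <- function(frames) {
  if (length(frames) < 1L) return("a movie needs at least one frame")
  if (!all(vapply(frames, is.matrix, logical(1))))
    return("all frames must be matrices")
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    return(sprintf("frame %d has a different shape than frame 1",
                   which(!same)[1L]))
  NULL
}

setValidity("PhaseMovie", function(object) {
  msg <- .validMovieFrames(object@frames)
  if (!is.null(msg)) return(msg)
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (anyNA(f) || any(f < 0) || any(f > 255) || any(f != round(f)))
      return(sprintf("frame %d is not 8-bit (integer values in [0, 255])", i))
  }
  TRUE
})

setValidity("FluorMovie", function(object) {
  msg <- .validMovieFrames(object@frames)
  if (!is.null(msg)) return(msg)
  if (any(vapply(object@frames, function(f) any(f < 0), logical(1))))
    return("fluorescence intensities must be non-negative")
  TRUE
})

#' Construct a PhaseMovie from a list of frames
#'
#' @param frames list of integer-valued matrices in [0, 255].
#' @param frameInterval minutes between frames (metadata).
#' @param pixelSize micrometers per pixel (metadata).
#' @return A [PhaseMovie-class] object.
#' @export
phaseMovie <- function(frames, frameInterval = NA_real_, pixelSize = NA_real_) {
  new("PhaseMovie", frames = frames, frameInterval = frameInterval,
      pixelSize = pixelSize)
}

#' Construct a FluorMovie from a list of frames
#'
#' @param frames list of non-negative real matrices.
#' @param channelName channel label, e.g. `"gfp"`.
#' @return A [FluorMovie-class] object.
#' @export
fluorMovie <- function(frames, channelName = "fluor") {
  new("FluorMovie", frames = frames, channelName = channelName)
}

#' Integer-labeled seed image
#'
#' A 2D integer matrix in which 0 is background and each positive value k
#' marks the pixels of cell k at the first segmented time point.  After
#' [finalizeSeed()] labels are consecutive 1..N, numbered left to right by
#' region centroid column.
#'
#' @slot labels integer matrix, 0 = background.
#' @exportClass SeedLabelImage
setClass("SeedLabelImage", representation(labels = "matrix"))

setValidity("SeedLabelImage", function(object) {
  L <- object@labels
  if (anyNA(L) || any(L < 0) || any(L != round(L)))
    return("labels must be non-negative integers")
  TRUE
})

#' @param labels integer matrix (0 = background, k > 0 = cell k).
#' @rdname SeedLabelImage-class
#' @export
seedLabelImage <- function(labels) {
  storage.mode(labels) <- "integer"
  new("SeedLabelImage", labels = labels)
}

#' Tracking parameters
#'
#' All numeric knobs of the segmentation/tracking pipeline.  The two
#' dual-threshold fractions (`lowFraction`, `highFraction`) are the only
#' parameters typically adjusted between experiments; the remaining values
#' are the method's standard settings.
#'
#' @slot lowFraction permissive dual-threshold fraction for pixels already in
#'   the seed (typical range 0.2--0.4; default 0.3).
#' @slot highFraction restrictive fraction for pixels outside the seed
#'   (default `lowFraction + 0.2`).
#' @slot growthFraction tolerated per-frame area growth before the thresholds
#'   are bumped once (typical 5--10\%; default 0.075).
#' @slot thresholdBump amount added to both fractions by the growth guard
#'   (fixed 0.2).
#' @slot minArea minimal allowed cell area in pixels (default 10).
#' @slot maxAreaFactor maximally allowed area as a multiple of the largest
#'   seeded cell (default 4/3).
#' @slot terminalGrowthFraction growth between consecutive frames that
#'   terminates a track (fixed 0.5, i.e. +50\%).
#' @slot windowPad padding in pixels added around the seed bounding box to
#'   form the segmentation window (default 10).
#' @slot phasePenaltyWeight multiplier applied to the raw 0--255 phase image
#'   before it is subtracted from the composite (default 0.25).
#' @slot scorePercentile percentile of window scores used as the
#'   normalization level (fixed 90).
#' @slot seedOverlapMin minimal fraction of a sub-region's area overlapping
#'   the seed for acceptance (fixed 0.40).
#' @slot noncellMax maximal fraction of a sub-region's area classified
#'   non-cell at the current threshold (fixed 1/3).
#' @exportClass TrackConfig
setClass("TrackConfig",
  representation(lowFraction = "numeric", highFraction = "numeric",
                 growthFraction = "numeric", thresholdBump = "numeric",
                 minArea = "numeric", maxAreaFactor = "numeric",
                 terminalGrowthFraction = "numeric", windowPad = "numeric",
                 phasePenaltyWeight = "numeric", scorePercentile = "numeric",
                 seedOverlapMin = "numeric", noncellMax = "numeric"))

setValidity("TrackConfig", function(object) {
  with_slots <- function(name) slot(object, name)
  for (nm in slotNames(object)) {
    v <- with_slots(nm)
    if (length(v) != 1L || !is.finite(v))
      return(sprintf("%s must be a single finite number", nm))
  }
  if (!(object@lowFraction > 0))
    return("0 < lowFraction is required")
  if (!(object@lowFraction < object@highFraction))
    return("lowFraction must be smaller than highFraction")
  if (!(object@highFraction <= 1))
    return("highFraction must be at most 1")
  if (object@minArea < 1)
    return("minArea must be at least 1 pixel")
  if (!(object@growthFraction > 0 &&
        object@growthFraction < object@terminalGrowthFraction))
    return("0 < growthFraction < terminalGrowthFraction is required")
  if (object@phasePenaltyWeight < 0)
    return("phasePenaltyWeight must be non-negative")
  if (object@windowPad < 0)
    return("windowPad must be non-negative")
  TRUE
})

#' Segmentation window around a seed
#'
#' The sub-region of a phase frame on which one cell/frame segmentation
#' runs: the seed's bounding box padded by `windowPad` pixels per side and
#' clipped to the frame.  `origin` gives the (row, col) of the window's
#' top-left pixel in full-frame coordinates.
#'
#' @slot origin integer (row, col) of the window's top-left corner.
#' @slot phase 8-bit phase sub-image.
#' @slot seedMask logical matrix, the previous segmentation cropped to the
#'   window; must be non-empty and of the same shape as `phase`.
#' @exportClass SegWindow
setClass("SegWindow",
  representation(origin = "integer", phase = "matrix", seedMask = "matrix"))

setValidity("SegWindow", function(object) {
  if (!identical(dim(object@phase), dim(object@seedMask)))
    return("phase and seedMask must have identical shape")
  if (!is.logical(object@seedMask))
    return("seedMask must be logical")
  if (!any(object@seedMask))
    return("seedMask must be non-empty")
  if (length(object@origin) != 2L)
    return("origin must be (row, col)")
  TRUE
})

#' Composite vote image
#'
#' Per-pixel count of how many of the 256 threshold-level watershed
#' segmentations accepted the pixel as part of the cell, and its
#' subsequently penalized versions.  `stage` tracks the processing state:
#' `"raw"` (integer votes in [0, 256]), `"distance_penalized"` (after the
#' movement penalty) or `"phase_penalized"` (after the boundary penalty).
#'
#' @slot scores real-valued matrix, window-shaped.
#' @slot stage one of `"raw"`, `"distance_penalized"`, `"phase_penalized"`.
#' @slot nThresholds number of threshold passes summed (256).
#' @exportClass CompositeScore
setClass("CompositeScore",
  representation(scores = "matrix", stage = "character",
                 nThresholds = "integer"))

setValidity("CompositeScore", function(object) {
  if (!object@stage %in% c("raw", "distance_penalized", "phase_penalized"))
    return("unknown stage")
  if (object@stage == "raw") {
    s <- object@scores
    if (any(s < 0) || any(s > 256) || any(s != round(s)))
      return("raw composite scores must be integers in [0, 256]")
  }
  TRUE
})

#' Backward track of a single cell
#'
#' Masks are stored sparsely as column-major pixel indices into the frame;
#' use [maskAt()] to reconstruct a logical matrix.  Frame indices form a
#' contiguous descending run starting at the seeded frame.
#'
#' @slot cellId seed label of the cell.
#' @slot frames integer vector of segmented frame indices, descending.
#' @slot maskIdx list (parallel to `frames`) of integer pixel-index vectors.
#' @slot frameDim (rows, cols) of the movie frames.
#' @slot seedIdx pixel indices of the initial seed mask.
#' @slot disappearanceFrame first frame, going backward, that was *not*
#'   segmented (where a termination rule fired), or `NULL` if the track
#'   reached the last requested frame.
#' @slot terminationReason one of `"too_small"`, `"too_large"`,
#'   `"growth_jump"`, `"reached_first_frame"`.
#' @exportClass CellTrack
setClass("CellTrack",
  representation(cellId = "integer", frames = "integer", maskIdx = "list",
                 frameDim = "integer", seedIdx = "integer",
                 disappearanceFrame = "integerOrNULL",
                 terminationReason = "character"))

setValidity("CellTrack", function(object) {
  if (length(object@frames) != length(object@maskIdx))
    return("frames and maskIdx must be parallel")
  if (length(object@frames) > 1L && any(diff(object@frames) != -1L))
    return("frames must form a contiguous descending run")
  if (any(vapply(object@maskIdx, length, integer(1)) == 0L))
    return("every stored mask must be non-empty")
  if (!object@terminationReason %in%
      c("too_small", "too_large", "growth_jump", "reached_first_frame"))
    return("unknown termination reason")
  TRUE
})

#' Result of tracking all seeded cells
#'
#' @slot tracks list of [CellTrack-class], one per seed label, ascending id.
#' @slot config the [TrackConfig-class] used.
#' @slot log data.frame of per-cell events (terminations, warnings).
#' @exportClass TrackingResult
setClass("TrackingResult",
  representation(tracks = "list", config = "TrackConfig", log = "data.frame"))

#' Synthetic colony parameters
#'
#' Defaults describe the study conditions the generator emulates: dark cell
#' interiors with 2-px bright halos on a mid-gray background, slow
#' exponential growth (1\% area per frame, far below a cell diameter),
#' occasional budding, sub-pixel frame-to-frame jitter and optional shmoo
#' elongation.
#'
#' @slot nInitialCells founder cells placed at frame 1.
#' @slot nFrames number of frames.
#' @slot frameShape (rows, cols) of each frame.
#' @slot interiorIntensity mean 8-bit intensity of cell interiors.
#' @slot haloIntensity mean intensity of the boundary halo ring.
#' @slot backgroundIntensity mean background intensity.
#' @slot noiseSd Gaussian pixel noise, intensity units.
#' @slot growthRate fractional area increase per frame.
#' @slot budProbability per eligible cell per frame probability of budding.
#' @slot jitterSd per-frame centre jitter in pixels (< 1).
#' @slot shmooFraction fraction of founders rendered with a shmoo
#'   protrusion.
#' @slot budInitialArea bud area at its birth frame, pixels.
#' @slot rngSeed integer seed; the generator is fully deterministic given it.
#' @exportClass ColonyParams
setClass("ColonyParams",
  representation(nInitialCells = "numeric", nFrames = "numeric",
                 frameShape = "numeric", interiorIntensity = "numeric",
                 haloIntensity = "numeric", backgroundIntensity = "numeric",
                 noiseSd = "numeric", growthRate = "numeric",
                 budProbability = "numeric", jitterSd = "numeric",
                 shmooFraction = "numeric", budInitialArea = "numeric",
                 rngSeed = "numeric"))

setValidity("ColonyParams", function(object) {
  if (!(object@interiorIntensity < object@backgroundIntensity &&
        object@backgroundIntensity < object@haloIntensity))
    return("interior < background < halo intensity is required")
  if (object@jitterSd >= 1)
    return("jitterSd must stay below 1 pixel per frame (immobility assumption)")
  if (object@growthRate < 0 || object@growthRate > 0.05)
    return("growthRate must be small (at most 5% area per frame)")
  if (object@nFrames < 1 || object@nInitialCells < 1)
    return("need at least one frame and one founder cell")
  if (length(object@frameShape) != 2L)
    return("frameShape must be (rows, cols)")
  TRUE
})

#' Ground truth of a synthetic colony movie
#'
#' @slot labelMovie list of integer label matrices, one per frame; the same
#'   id denotes the same cell in every frame.
#' @slot lineage data.frame with columns `id`, `birthFrame`, `motherId`
#'   (`NA` for founders).
#' @slot nuclei data.frame with per cell per frame nucleus truth: `frame`,
#'   `id`, `centerRow`, `centerCol`, `gfpAmplitude`, `redAmplitude`,
#'   `sigma`.
#' @slot focusEpisodes data.frame with columns `id`, `start`, `end`,
#'   `dimFraction` describing focus-drift dimming of the red channel.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(labelMovie = "list", lineage = "data.frame",
                 nuclei = "data.frame", focusEpisodes = "data.frame"))

#' Segmentation error-taxonomy summary
#'
#' Aggregate of per-cell-frame classifications: a segmentation is *proper*
#' if its area-correctness exceeds 0.95, a *minor* error at 0.90--0.95 and a
#' *major* error below 0.90.
#'
#' @slot nCells number of evaluated tracks.
#' @slot nSegmentations number of evaluated cell-frames.
#' @slot fractionProper,fractionMinor,fractionMajor the three fractions
#'   (they sum to 1).
#' @slot fractionErrorFreeTracks fraction of tracks whose every frame is
#'   proper.
#' @slot perCell per-track detail data.frame (truth id, counts, birth
#'   frames).
#' @exportClass TrackingSummary
setClass("TrackingSummary",
  representation(nCells = "integer", nSegmentations = "integer",
                 fractionProper = "numeric", fractionMinor = "numeric",
                 fractionMajor = "numeric",
                 fractionErrorFreeTracks = "numeric", perCell = "data.frame"))
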