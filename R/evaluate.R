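# Evaluation against ground truth with the proper/minor/major segmentation
# error taxonomy.

#' Classify a single segmentation against truth
#'
#' Area-correctness is operationalized as intersection-over-union
#' (`|mask & truth| / |mask | truth|`), which penalizes both under- and
#' over-segmentation with one number and is symmetric in its arguments; the
#' alternative reading (fraction of the *truth* area covered,
#' `|mask & truth| / |truth|`) is available via `method =
#' "truth_fraction"`.  A segmentation is `"proper"` when correctness
#' exceeds 0.95, a `"minor"` error at 0.90--0.95, and a `"major"` error
#' below 0.90; an empty mask is a major error by definition.
#'
#' @param mask logical matrix, the segmentation.
#' @param truthMask logical matrix, non-empty ground truth.
#' @param method `"iou"` (default) or `"truth_fraction"`.
#' @return `"proper"`, `"minor"` or `"major"`.
#' @export
classifySegmentation <- function(mask, truthMask,
                                 method = c("iou", "truth_fraction")) {
  method <- match.arg(method)
  stopifnot(identical(dim(mask), dim(truthMask)))
  if (!any(truthMask)) stop("truth mask must be non-empty")
  inter <- sum(mask & truthMask)
  corr <- if (method == "iou") {
    uni <- sum(mask | truthMask)
    inter / uni
  } else {
    inter / sum(truthMask)
  }
  if (corr > 0.95) "proper" else if (corr >= 0.90) "minor" else "major"
}

#' Summarize a tracking run against ground truth
#'
#' Each track is matched to a truth cell by maximal overlap of its initial
#' seed mask with the truth labels at the seeded frame.  Every stored
#' cell-frame is classified with [classifySegmentation()] (frames the track
#' stored but where the truth cell does not exist count as major errors),
#' and the classifications aggregate into the four taxonomy fractions.  The
#' per-cell table also reports, for every matched truth cell, its true
#' birth frame and the detected one (`disappearanceFrame + 1`, or the
#' lowest tracked frame for completed tracks), which [birthRecoveryRate()]
#' turns into a recovery statistic for buds.
#'
#' @param result a [TrackingResult-class].
#' @param truth a [GroundTruth-class] covering all tracked frames.
#' @param method correctness measure, see [classifySegmentation()].
#' @return A [TrackingSummary-class].
#' @export
summarizeTracking <- function(result, truth, method = c("iou",
                                                        "truth_fraction")) {
  method <- match.arg(method)
  stopifnot(is(result, "TrackingResult"), is(truth, "GroundTruth"))
  labs <- truth@labelMovie
  perCell <- list()
  for (tr in result@tracks) {
    d <- tr@frameDim
    seededFrame <- if (length(tr@frames)) tr@frames[1L]
                   else length(labs)
    truthAtSeed <- labs[[seededFrame]]
    v <- truthAtSeed[tr@seedIdx]
    v <- v[v > 0L]
    if (!length(v))
      stop("track ", tr@cellId, " matches no truth cell at its seeded frame")
    truthId <- as.integer(names(which.max(table(v))))
    birthTrue <- truth@lineage$birthFrame[truth@lineage$id == truthId]
    if (!length(birthTrue))
      stop("cell id ", truthId, " absent from truth lineage")

    nProper <- nMinor <- nMajor <- 0L
    for (k in seq_along(tr@frames)) {
      f <- tr@frames[k]
      mask <- matrix(FALSE, d[1L], d[2L])
      mask[tr@maskIdx[[k]]] <- TRUE
      tm <- labs[[f]] == truthId
      if (!any(tm)) { nMajor <- nMajor + 1L; next }
      cls <- classifySegmentation(mask, tm, method)
      if (cls == "proper") nProper <- nProper + 1L
      else if (cls == "minor") nMinor <- nMinor + 1L
      else nMajor <- nMajor + 1L
    }
    birthDetected <- if (!is.null(tr@disappearanceFrame))
      tr@disappearanceFrame + 1L
    else if (length(tr@frames)) tr@frames[length(tr@frames)]
    else NA_integer_
    perCell[[length(perCell) + 1L]] <- data.frame(
      cellId = tr@cellId, truthId = truthId,
      nFrames = length(tr@frames), nProper = nProper, nMinor = nMinor,
      nMajor = nMajor, birthTrue = birthTrue,
      birthDetected = birthDetected,
      terminationReason = tr@terminationReason)
  }
  pc <- do.call(rbind, perCell)
  nSeg <- sum(pc$nFrames)
  if (nSeg == 0L) stop("no stored segmentations to summarize")
  new("TrackingSummary",
      nCells = nrow(pc), nSegmentations = as.integer(nSeg),
      fractionProper = sum(pc$nProper) / nSeg,
      fractionMinor = sum(pc$nMinor) / nSeg,
      fractionMajor = sum(pc$nMajor) / nSeg,
      fractionErrorFreeTracks = mean(pc$nProper == pc$nFrames),
      perCell = pc)
}

#' Bud birth-frame recovery rate
#'
#' Among matched truth cells born after the first frame (buds), the
#' fraction whose detected birth frame lies within `tol` frames of the true
#' one.
#'
#' @param summary a [TrackingSummary-class].
#' @param tol tolerance in frames (default 1).
#' @return A list with `rate`, `nBuds` and the per-bud error vector.
#' @export
birthRecoveryRate <- function(summary, tol = 1L) {
  stopifnot(is(summary, "TrackingSummary"))
  pc <- summary@perCell
  buds <- pc[pc$birthTrue > 1L, , drop = FALSE]
  if (!nrow(buds)) return(list(rate = NA_real_, nBuds = 0L, errors = integer(0)))
  err <- abs(buds$birthDetected - buds$birthTrue)
  list(rate = mean(err <= tol), nBuds = nrow(buds), errors = err)
}

#' Sorted trace lengths for survival-style plots
#'
#' @param summary a [TrackingSummary-class].
#' @return Integer vector of per-cell segmented-frame counts, decreasing.
#' @export
traceLengths <- function(summary) {
  stopifnot(is(summary, "TrackingSummary"))
  sort(summary@perCell$nFrames, decreasing = TRUE)
}

#' Export a summary as a Table-1-style CSV
#'
#' @param summary a [TrackingSummary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSummary <- function(summary, path) {
  df <- data.frame(
    statistic = c("Total number of segmented cells",
                  "Mean segmented frames per cell",
                  "Total number of segmentation events",
                  "Fraction of accurate segmentations",
                  "Fraction of minor segmentation errors",
                  "Fraction of major segmentation errors",
                  "Fraction of individual time-series without any errors"),
    value = c(summary@nCells,
              round(summary@nSegmentations / summary@nCells, 1),
              summary@nSegmentations,
              summary@fractionProper, summary@fractionMinor,
              summary@fractionMajor, summary@fractionErrorFreeTracks))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
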