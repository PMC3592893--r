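# The voting core: one cell, one frame.  All 256 intensity thresholds are
# applied to the window, each binary image is watershed-partitioned, every
# sub-region is scored against the seed, and the accepted regions are summed
# into the composite score image.

#' Binarize a phase window at one threshold
#'
#' A pixel is a candidate "cell" pixel at threshold `t` iff its intensity is
#' strictly below `t`.  Thresholds run 1..256 so that `t = 256` marks every
#' 8-bit pixel as candidate and a pixel accepted at every pass can reach the
#' maximal vote of 256.
#'
#' @param phase 8-bit integer matrix.
#' @param t threshold in 1..256.
#' @return Logical candidate matrix.
#' @export
binarizeAtThreshold <- function(phase, t) {
  stopifnot(is.matrix(phase))
  if (length(t) != 1L || is.na(t) || t != round(t) || t < 1 || t > 256)
    stop("threshold must be a single integer in [1, 256]")
  phase < t
}

#' Partition a candidate mask into watershed sub-regions
#'
#' Computes the exact Euclidean distance transform of the candidate mask
#' (distance to the nearest non-candidate pixel) and floods the basins of
#' its negation, Meyer-style, with non-candidate pixels excluded from the
#' flooding.  Every candidate pixel ends up in exactly one sub-region.
#' Basin seeds are the regional maxima plateaus of the distance transform;
#' flooding ties are resolved deterministically to the basin whose seed
#' plateau starts first in row-major order.
#'
#' @param candidate logical matrix.
#' @return Integer matrix of sub-region labels; non-candidate pixels are 0.
#' @export
watershedSubregions <- function(candidate) {
  stopifnot(is.matrix(candidate), is.logical(candidate))
  if (anyNA(candidate)) stop("candidate must not contain NA")
  .watershedCpp(candidate)
}

#' Score one watershed sub-region as cell or non-cell
#'
#' A sub-region scores 1 iff (i) more than `seedOverlapMin` of its area
#' overlaps the seed, (ii) less than `noncellMax` of its area consists of
#' non-candidate pixels at the current threshold, and (iii) no pixel of the
#' region lies on the window's outermost row or column.
#'
#' @param region logical matrix (non-empty).
#' @param seedMask logical matrix, the seed cropped to the window.
#' @param candidate logical matrix from [binarizeAtThreshold()].
#' @param cfg a [TrackConfig-class].
#' @return 1L or 0L.
#' @export
scoreSubregion <- function(region, seedMask, candidate, cfg = trackConfig()) {
  stopifnot(identical(dim(region), dim(seedMask)),
            identical(dim(region), dim(candidate)))
  a <- sum(region)
  if (a == 0L) stop("region must be non-empty")
  overlap <- sum(region & seedMask) / a
  noncell <- sum(region & !candidate) / a
  nr <- nrow(region); nc <- ncol(region)
  onBorder <- any(region[1L, ]) || any(region[nr, ]) ||
    any(region[, 1L]) || any(region[, nc])
  if (overlap > cfg@seedOverlapMin && noncell < cfg@noncellMax && !onBorder)
    1L else 0L
}

#' Extract the segmentation window around a seed
#'
#' The window is the bounding box of the seed mask padded by
#' `cfg@windowPad` pixels per side, clipped to the frame.
#'
#' @param frame 8-bit phase frame (integer matrix).
#' @param seedFull logical full-frame seed mask (non-empty).
#' @param cfg a [TrackConfig-class].
#' @return A [SegWindow-class].
#' @export
makeWindow <- function(frame, seedFull, cfg = trackConfig()) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(seedFull)))
  bb <- .maskBBox(seedFull)
  if (is.null(bb)) stop("seed mask is empty")
  pad <- as.integer(cfg@windowPad)
  r1 <- max(1L, bb[1L] - pad); r2 <- min(nrow(frame), bb[2L] + pad)
  c1 <- max(1L, bb[3L] - pad); c2 <- min(ncol(frame), bb[4L] + pad)
  new("SegWindow", origin = c(r1, c1),
      phase = frame[r1:r2, c1:c2, drop = FALSE],
      seedMask = seedFull[r1:r2, c1:c2, drop = FALSE])
}

#' Sum accepted watershed regions over all 256 thresholds
#'
#' For every threshold t in 1..256 the window is binarized, partitioned by
#' [watershedSubregions()], each sub-region is scored by the three criteria
#' of [scoreSubregion()], and the union of accepted regions adds one vote to
#' its pixels.  The result is the raw composite score image: integer votes
#' between 0 and 256.
#'
#' @param window a [SegWindow-class].
#' @param cfg a [TrackConfig-class].
#' @return A [CompositeScore-class] at stage `"raw"`.
#' @export
compositeSweep <- function(window, cfg = trackConfig()) {
  stopifnot(is(window, "SegWindow"))
  validObject(window)
  ph <- window@phase
  storage.mode(ph) <- "integer"
  raw <- .compositeSweepCpp(ph, window@seedMask,
                            cfg@seedOverlapMin, cfg@noncellMax)
  new("CompositeScore", scores = raw, stage = "raw", nThresholds = 256L)
}
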