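# Refinement of the raw composite into the final per-frame segmentation:
# movement penalty, boundary penalty, percentile-normalized dual
# thresholding, one-time growth guard and connectivity filter.

#' Penalize cell movement
#'
#' Subtracts from each pixel's composite score its Euclidean distance (in
#' pixels) to the nearest seed pixel; pixels inside the seed are unchanged
#' (distance 0).  Movement of the mask away from the previous segmentation
#' is thereby penalized in proportion to how far it strays.
#'
#' @param score a [CompositeScore-class] at stage `"raw"`.
#' @param seedMask logical matrix, window-shaped.
#' @return A [CompositeScore-class] at stage `"distance_penalized"`.
#' @export
distancePenalty <- function(score, seedMask) {
  stopifnot(is(score, "CompositeScore"))
  if (score@stage != "raw")
    stop("distancePenalty expects a raw composite, got stage '",
         score@stage, "'")
  stopifnot(identical(dim(score@scores), dim(seedMask)))
  d <- distanceTransform(!seedMask)  # distance to nearest seed pixel
  new("CompositeScore", scores = score@scores - d,
      stage = "distance_penalized", nThresholds = score@nThresholds)
}

#' Penalize bright phase regions
#'
#' Subtracts the rescaled phase image (`phasePenaltyWeight` times the native
#' 0--255 intensities) from the composite, so that bright boundary halos
#' cannot be scored as cell.
#'
#' @param score a [CompositeScore-class] at stage `"distance_penalized"`.
#' @param phase 8-bit integer matrix, window-shaped.
#' @param cfg a [TrackConfig-class].
#' @return A [CompositeScore-class] at stage `"phase_penalized"`.
#' @export
phasePenalty <- function(score, phase, cfg = trackConfig()) {
  stopifnot(is(score, "CompositeScore"))
  if (score@stage != "distance_penalized")
    stop("phasePenalty expects a distance-penalized composite, got stage '",
         score@stage, "'")
  stopifnot(identical(dim(score@scores), dim(phase)))
  new("CompositeScore",
      scores = score@scores - cfg@phasePenaltyWeight * phase,
      stage = "phase_penalized", nThresholds = score@nThresholds)
}

#' Dual-threshold segmentation of the penalized composite
#'
#' The scores are normalized by their `scorePercentile`-th percentile P over
#' the whole window (negatives included).  A pixel joins the putative
#' segmentation if (i) its score is at least `(lowFraction + bump) * P` AND
#' it lies in the seed, or (ii) its score is at least
#' `(highFraction + bump) * P` regardless of the seed -- new growth is
#' admitted, but at the stricter threshold.  A degenerate window with
#' P <= 0 returns an empty mask with a warning (the thresholds would invert
#' their meaning on a non-positive normalization level); downstream this
#' terminates the track.
#'
#' @param score a [CompositeScore-class] at stage `"phase_penalized"`.
#' @param seedMask logical window-shaped matrix.
#' @param cfg a [TrackConfig-class].
#' @param bump addition to both fractions (used by [growthGuard()]).
#' @return A list with elements `mask` (logical matrix) and `rethresholded`
#'   (logical flag, `TRUE` iff `bump > 0`).
#' @export
dualThreshold <- function(score, seedMask, cfg = trackConfig(), bump = 0) {
  stopifnot(is(score, "CompositeScore"))
  if (score@stage != "phase_penalized")
    stop("dualThreshold expects a phase-penalized composite, got stage '",
         score@stage, "'")
  stopifnot(identical(dim(score@scores), dim(seedMask)))
  s <- score@scores
  P <- as.numeric(stats::quantile(s, cfg@scorePercentile / 100,
                                  names = FALSE))
  if (P <= 0) {
    warning("degenerate window: score percentile is not positive")
    return(list(mask = matrix(FALSE, nrow(s), ncol(s)),
                rethresholded = bump > 0))
  }
  mask <- (s >= (cfg@lowFraction + bump) * P & seedMask) |
          (s >= (cfg@highFraction + bump) * P)
  list(mask = mask, rethresholded = bump > 0)
}

#' One-time growth guard
#'
#' If the putative segmentation has grown by more than `growthFraction`
#' relative to the seed area, both dual-threshold fractions are increased by
#' `thresholdBump` and the thresholding is repeated -- once only, to prevent
#' uncontrolled growth.  A putative segmentation that is still larger after
#' the bump is accepted as is.
#'
#' @param putative result of [dualThreshold()].
#' @param seedMask logical window-shaped matrix.
#' @param score the [CompositeScore-class] (stage `"phase_penalized"`) the
#'   putative mask came from.
#' @param cfg a [TrackConfig-class].
#' @return A putative-segmentation list as from [dualThreshold()].
#' @export
growthGuard <- function(putative, seedMask, score, cfg = trackConfig()) {
  if (isTRUE(putative$rethresholded)) return(putative)
  if (sum(putative$mask) > (1 + cfg@growthFraction) * sum(seedMask))
    dualThreshold(score, seedMask, cfg, bump = cfg@thresholdBump)
  else putative
}

#' Keep only the largest connected component
#'
#' Retains the largest 8-connected sub-object of the putative segmentation
#' and discards all others; among equally large components the one whose
#' first pixel comes earliest in row-major order wins.  An empty mask
#' passes through empty.
#'
#' @param putative a putative-segmentation list (or a bare logical matrix).
#' @return The same structure with the mask reduced to one component.
#' @export
largestComponent <- function(putative) {
  bare <- is.matrix(putative)
  mask <- if (bare) putative else putative$mask
  lab <- labelComponents(mask)
  n <- max(lab)
  if (n > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    best <- which.max(sizes)  # first maximum = earliest row-major component
    mask <- lab == best
  }
  if (bare) mask else { putative$mask <- mask; putative }
}

# Full refinement pipeline for one window: raw composite -> final mask.
.refineWindow <- function(raw, window, cfg) {
  dp <- distancePenalty(raw, window@seedMask)
  pp <- phasePenalty(dp, window@phase, cfg)
  put <- withCallingHandlers(
    dualThreshold(pp, window@seedMask, cfg),
    warning = function(w) invokeRestart("muffleWarning"))
  put <- growthGuard(put, window@seedMask, pp, cfg)
  put <- largestComponent(put)
  put$mask
}
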