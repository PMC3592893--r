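#' Construct a tracking configuration
#'
#' Returns a validated [TrackConfig-class].  Defaults are the method's
#' standard settings; `highFraction` defaults to `lowFraction + 0.2`.  The
#' fixed parameters (`thresholdBump`, `terminalGrowthFraction`,
#' `scorePercentile`, `seedOverlapMin`, `noncellMax`) are part of the method
#' definition and rarely changed.
#'
#' @param lowFraction permissive dual-threshold fraction (default 0.3).
#' @param highFraction restrictive fraction (default `lowFraction + 0.2`).
#' @param growthFraction tolerated per-frame growth before the one-time
#'   threshold bump (default 0.075).
#' @param thresholdBump one-time addition to both fractions (0.2).
#' @param minArea minimal cell area, pixels (default 10).
#' @param maxAreaFactor maximal area as multiple of the largest seed (4/3).
#' @param terminalGrowthFraction growth jump that terminates a track (0.5).
#' @param windowPad window padding around the seed bounding box, pixels
#'   (default 10).
#' @param phasePenaltyWeight weight of the phase-image penalty (default
#'   0.25).
#' @param scorePercentile normalization percentile (90).
#' @param seedOverlapMin minimal seed-overlap fraction of a sub-region
#'   (0.40).
#' @param noncellMax maximal non-cell fraction of a sub-region (1/3).
#' @return A [TrackConfig-class] object.
#' @examples
#' cfg <- trackConfig(lowFraction = 0.25)
#' cfg
#' @export
trackConfig <- function(lowFraction = 0.3,
                        highFraction = lowFraction + 0.2,
                        growthFraction = 0.075,
                        thresholdBump = 0.2,
                        minArea = 10,
                        maxAreaFactor = 4 / 3,
                        terminalGrowthFraction = 0.5,
                        windowPad = 10,
                        phasePenaltyWeight = 0.25,
                        scorePercentile = 90,
                        seedOverlapMin = 0.40,
                        noncellMax = 1 / 3) {
  new("TrackConfig",
      lowFraction = lowFraction, highFraction = highFraction,
      growthFraction = growthFraction, thresholdBump = thresholdBump,
      minArea = minArea, maxAreaFactor = maxAreaFactor,
      terminalGrowthFraction = terminalGrowthFraction, windowPad = windowPad,
      phasePenaltyWeight = phasePenaltyWeight,
      scorePercentile = scorePercentile, seedOverlapMin = seedOverlapMin,
      noncellMax = noncellMax)
}

#' Load a tracking configuration from a file
#'
#' Reads a flat key-value YAML file whose keys mirror the [trackConfig()]
#' argument names exactly.  Unspecified keys take the documented defaults;
#' an empty file yields the full default configuration.  Unknown keys are an
#' error (listing the valid keys), as is any violated invariant.
#'
#' @param path path to the config file.
#' @return A validated [TrackConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  valid <- names(formals(trackConfig))
  bad <- setdiff(names(vals), valid)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L,
                  logical(1))))
    stop("all config values must be single numbers")
  do.call(trackConfig, vals)
}

#' Write a tracking configuration to a file
#'
#' @param cfg a [TrackConfig-class].
#' @param path output path (flat YAML).
#' @return `path`, invisibly.
#' @export
writeConfig <- function(cfg, path) {
  stopifnot(is(cfg, "TrackConfig"))
  vals <- lapply(slotNames(cfg), function(nm) slot(cfg, nm))
  names(vals) <- slotNames(cfg)
  yaml::write_yaml(vals, path, precision = 15L)
  invisible(path)
}
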