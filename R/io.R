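# Movie and label-image I/O.  Multi-page grayscale TIFF for images, RFC-4180
# CSV for tables.  All phase input is normalized to the package-wide 8-bit
# convention on read.

#' Read a movie from a TIFF stack
#'
#' Reads a multi-page grayscale TIFF (or a directory of single-page TIFFs in
#' lexicographic frame order).  Phase movies are converted to 8-bit: input
#' that is already integer-valued in [0, 255] passes through unchanged
#' (conversion is idempotent); higher-depth input is linearly rescaled using
#' the global 0.1st and 99.9th intensity percentiles across the whole movie,
#' clipped outside that range and rounded half-up.  The movie-global rule
#' keeps a given threshold meaning the same thing in every frame and is
#' robust to hot pixels.  Fluorescence movies keep their native values as
#' reals.
#'
#' @param path TIFF stack or directory of TIFFs.
#' @param channel `"phase"` or `"fluor"`.
#' @param channelName label stored in a [FluorMovie-class].
#' @param frameInterval,pixelSize optional metadata for phase movies.
#' @return A [PhaseMovie-class] or [FluorMovie-class].
#' @export
readMovie <- function(path, channel = c("phase", "fluor"),
                      channelName = "fluor", frameInterval = NA_real_,
                      pixelSize = NA_real_) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  frames <- .readFrames(path)
  d <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has shape %s, expected %s", i,
                   paste(dim(frames[[i]]), collapse = "x"),
                   paste(d, collapse = "x")))
  if (channel == "phase") {
    frames <- .toEightBit(frames)
    phaseMovie(frames, frameInterval = frameInterval, pixelSize = pixelSize)
  } else {
    fluorMovie(frames, channelName = channelName)
  }
}

.readFrames <- function(path) {
  readOne <- function(p) {
    x <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(x)) x <- list(x)
    lapply(x, function(f) {
      if (length(dim(f)) == 3L) {
        if (dim(f)[3L] == 1L) f <- f[, , 1L]
        else stop("expected grayscale TIFF, got ", dim(f)[3L], " channels")
      }
      f
    })
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files in directory: ", path)
    do.call(c, lapply(files, readOne))
  } else {
    readOne(path)
  }
}

# Movie-global 8-bit conversion (see readMovie docs).
.toEightBit <- function(frames) {
  allv <- unlist(lapply(frames, as.vector), use.names = FALSE)
  isInt <- all(allv == round(allv))
  if (isInt && min(allv) >= 0 && max(allv) <= 255)
    return(lapply(frames, function(f) { storage.mode(f) <- "integer"; f }))
  lo <- as.numeric(stats::quantile(allv, 0.001, names = FALSE))
  hi <- as.numeric(stats::quantile(allv, 0.999, names = FALSE))
  if (hi <= lo) hi <- lo + 1
  lapply(frames, function(f) {
    g <- (f - lo) / (hi - lo) * 255
    g[g < 0] <- 0
    g[g > 255] <- 255
    g <- floor(g + 0.5)  # round half-up
    storage.mode(g) <- "integer"
    g
  })
}

#' Write a tracking result as a label stack plus index CSV
#'
#' Writes one 16-bit label frame per time point (cell k as pixel value k)
#' covering frames 1 to the highest segmented frame, and a CSV (columns
#' `cell_id`, `first_frame_segmented`, `disappearance_frame`,
#' `termination_reason`) next to it.  Where two cells' masks overlap in a
#' frame the lower cell id wins and a warning is logged.
#'
#' @param result a [TrackingResult-class] with at least one segmented frame.
#' @param path output TIFF path; the CSV is written to the same path with
#'   `_index.csv` substituted for the extension.
#' @return Invisibly, a list with elements `tiff` and `csv`.
#' @export
writeLabels <- function(result, path) {
  stopifnot(is(result, "TrackingResult"))
  trs <- result@tracks
  if (!length(trs) || all(vapply(trs, function(t) length(t@frames),
                                 integer(1)) == 0L))
    stop("tracking produced no segmentations to write")
  d <- trs[[which(vapply(trs, function(t) length(t@frames) > 0L,
                         logical(1)))[1L]]]@frameDim
  maxFrame <- max(unlist(lapply(trs, function(t) t@frames)))
  stack <- vector("list", maxFrame)
  for (f in seq_len(maxFrame)) {
    lab <- matrix(0L, d[1L], d[2L])
    total <- 0L
    # higher ids first so that the lower id overwrites on overlap
    for (t in rev(trs)) {
      k <- match(f, t@frames)
      if (is.na(k)) next
      lab[t@maskIdx[[k]]] <- t@cellId
      total <- total + length(t@maskIdx[[k]])
    }
    if (sum(lab > 0L) < total)
      warning(sprintf("frame %d: overlapping cell masks; lower id kept", f))
    stack[[f]] <- lab
  }
  tiff::writeTIFF(lapply(stack, function(m) m / 65535), path,
                  bits.per.sample = 16L)
  csv <- paste0(tools::file_path_sans_ext(path), "_index.csv")
  idx <- data.frame(
    cell_id = vapply(trs, cellId, integer(1)),
    first_frame_segmented = vapply(trs, function(t)
      if (length(t@frames)) t@frames[1L] else NA_integer_, integer(1)),
    disappearance_frame = vapply(trs, function(t)
      if (is.null(t@disappearanceFrame)) NA_integer_
      else t@disappearanceFrame, integer(1)),
    termination_reason = vapply(trs, terminationReason, character(1)))
  utils::write.csv(idx, csv, row.names = FALSE)
  invisible(list(tiff = path, csv = csv))
}

#' Read a label stack written by [writeLabels()] (or any 16-bit label TIFF)
#'
#' @param path multi-page label TIFF.
#' @return A list of integer label matrices, one per frame.
#' @export
readLabels <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(f) { storage.mode(f) <- "integer"; f })
}

# Write a list of integer frames as a grayscale TIFF stack.
.writeStack <- function(frames, path, bits = 8L) {
  mx <- 2^bits - 1
  tiff::writeTIFF(lapply(frames, function(f) {
    g <- pmin(pmax(f, 0), mx) / mx
    g
  }), path, bits.per.sample = as.integer(bits))
  invisible(path)
}
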