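# Feature extraction: per-cell per-frame morphology from the masks, nuclear
# fluorescence via averaging filter + brightest-25% nucleus + 2D Gaussian
# fit, and reference-channel out-of-focus correction.

#' Morphological features of a cell mask
#'
#' Area is the pixel count; the centroid is the mean pixel coordinate;
#' major/minor axis lengths are those of the ellipse with the same second
#' central moments as the mask (4 times the square roots of the covariance
#' eigenvalues, the standard region-properties convention); the
#' circumference is the length of the 8-connected boundary contour with
#' diagonal steps weighted sqrt(2).
#'
#' @param mask non-empty logical matrix (one connected cell).
#' @return A list with `area`, `centroid` (row, col), `majorAxis`,
#'   `minorAxis`, `circumference`.
#' @export
morphology <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  if (n == 0L) stop("mask is empty")
  cr <- mean(w[, 1L]); cc <- mean(w[, 2L])
  dr <- w[, 1L] - cr; dc <- w[, 2L] - cc
  covm <- matrix(c(mean(dr * dr), mean(dr * dc),
                   mean(dr * dc), mean(dc * dc)), 2L, 2L)
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  list(area = n,
       centroid = c(cr, cc),
       majorAxis = 4 * sqrt(ev[1L]),
       minorAxis = 4 * sqrt(ev[2L]),
       circumference = .moorePerimeter(mask))
}

# Perimeter by Moore contour tracing (Jacob's stopping criterion: stop when
# the trace leaves the start pixel in the same direction as the first move);
# diagonal steps count sqrt(2), axial steps 1.  A single pixel has perimeter
# 4 (its pixel-boundary length).
.moorePerimeter <- function(mask) {
  n <- sum(mask)
  if (n == 1L) return(4)
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # clockwise neighbourhood starting west
  dirs <- cbind(c(0, -1, -1, -1, 0, 1, 1, 1), c(-1, -1, 0, 1, 1, 1, 0, -1))
  w <- which(p, arr.ind = TRUE)
  start <- w[order(w[, 1L], w[, 2L]), , drop = FALSE][1L, ]
  cur <- start
  backtrack <- 1L  # the scan starts at the background pixel west of start
  perim <- 0
  firstMove <- NA_integer_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 8L * n + 8L) break  # safety cap
    move <- NA_integer_
    for (k in 0:7) {
      j <- ((backtrack - 1L + k) %% 8L) + 1L
      q <- c(cur[1L] + dirs[j, 1L], cur[2L] + dirs[j, 2L])
      if (p[q[1L], q[2L]]) { move <- j; break }
    }
    if (is.na(move)) break
    if (!is.na(firstMove) && all(cur == start) && move == firstMove)
      break  # contour closed
    if (is.na(firstMove)) firstMove <- move
    perim <- perim + if (all(abs(dirs[move, ]) == 1L)) sqrt(2) else 1
    # new backtrack: the background neighbour scanned just before the hit,
    # expressed relative to the new pixel
    prevJ <- ((move - 2L) %% 8L) + 1L
    bgd <- c(cur[1L] + dirs[prevJ, 1L] - q[1L],
             cur[2L] + dirs[prevJ, 2L] - q[2L])
    backtrack <- which(dirs[, 1L] == bgd[1L] & dirs[, 2L] == bgd[2L])
    cur <- q
  }
  perim
}

#' Nuclear fluorescence of one cell
#'
#' The fluorescence window is smoothed with a 3x3 box averaging filter; the
#' peak is the brightest smoothed pixel inside the cell mask; the nucleus
#' mask is the brightest 25\% of cell pixels by smoothed intensity
#' (`round(0.25 * area)` pixels, ties broken in row-major order); a 2D
#' elliptical Gaussian with constant offset is least-squares fitted over a
#' square patch centered on the peak (clipped to the cell's bounding box).
#' The reported `nuclearMean` is the mean *raw* intensity over the nucleus
#' mask.  A non-converging fit keeps the peak and nuclear mean and flags the
#' Gaussian parameters as absent; it never aborts a pipeline run.
#'
#' @param fluorWindow numeric matrix of fluorescence intensities.
#' @param cellMask non-empty logical matrix, same shape.
#' @param filterSize box filter side length (default 3).
#' @param patchHalf half-width of the Gaussian fit patch (default 7, i.e.
#'   15x15).
#' @return A list with `peak` (row, col), `nuclearMean`, `nucleusMask`,
#'   `nucleusArea` and `gaussian` (named vector `amplitude`, `centerRow`,
#'   `centerCol`, `sigmaRow`, `sigmaCol`, `offset`, or `NULL` if the fit
#'   failed).
#' @export
nuclearSignal <- function(fluorWindow, cellMask, filterSize = 3L,
                          patchHalf = 7L) {
  stopifnot(identical(dim(fluorWindow), dim(cellMask)))
  if (!any(cellMask)) stop("cell mask is empty")
  sm <- .boxFilter(fluorWindow, filterSize)

  inside <- which(cellMask)
  peakIdx <- inside[which.max(sm[inside])]
  peak <- c((peakIdx - 1L) %% nrow(sm) + 1L,
            (peakIdx - 1L) %/% nrow(sm) + 1L)

  area <- length(inside)
  k <- max(1L, as.integer(round(0.25 * area)))
  ord <- inside[order(-sm[inside], inside)]
  nucIdx <- ord[seq_len(k)]
  nucleusMask <- matrix(FALSE, nrow(sm), ncol(sm))
  nucleusMask[nucIdx] <- TRUE
  nuclearMean <- mean(fluorWindow[nucIdx])

  bb <- .maskBBox(cellMask)
  r1 <- max(bb[1L], peak[1L] - patchHalf); r2 <- min(bb[2L], peak[1L] + patchHalf)
  c1 <- max(bb[3L], peak[2L] - patchHalf); c2 <- min(bb[4L], peak[2L] + patchHalf)
  patch <- fluorWindow[r1:r2, c1:c2, drop = FALSE]
  gaussian <- .fitGaussian2D(patch, offsetRow = r1 - 1L, offsetCol = c1 - 1L,
                             peak = peak)

  list(peak = peak, nuclearMean = nuclearMean, nucleusMask = nucleusMask,
       nucleusArea = k, gaussian = gaussian)
}

# Box mean filter; border pixels average over their in-bounds neighbourhood.
.boxFilter <- function(m, size = 3L) {
  h <- (size - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  acc / cnt
}

.fitGaussian2D <- function(patch, offsetRow, offsetCol, peak) {
  rr <- as.vector(row(patch)) + offsetRow
  cc <- as.vector(col(patch)) + offsetCol
  v <- as.vector(patch)
  med <- stats::median(v)
  start <- list(A = max(v[rr == peak[1L] & cc == peak[2L]], 0) ,
                r0 = peak[1L], c0 = peak[2L], sr = 2, sc = 2, b = med)
  start$A <- max(start$A - med, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-((rr - r0)^2 / (2 * sr^2) + (cc - c0)^2 / (2 * sc^2))) + b,
      start = start,
      lower = c(A = 0, r0 = min(rr), c0 = min(cc), sr = 0.3, sc = 0.3,
                b = -Inf),
      upper = c(A = Inf, r0 = max(rr), c0 = max(cc), sr = Inf, sc = Inf,
                b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  c(amplitude = unname(cf["A"]), centerRow = unname(cf["r0"]),
    centerCol = unname(cf["c0"]), sigmaRow = unname(cf["sr"]),
    sigmaCol = unname(cf["sc"]), offset = unname(cf["b"]))
}

#' Out-of-focus correction of a nuclear signal
#'
#' Uses a constant-brightness nuclear reference channel (e.g. a histone
#' fusion) to detect episodes in which the nucleus drifts out of the focal
#' plane.  The reference trace is smoothed with a centered moving average
#' (window 3); within each contiguous dimming episode the reference level is
#' the pre-dip smoothed value, and wherever the smoothed reference falls
#' below that level the signal is multiplied by
#' `1 + coefficient * (reference/smoothed - 1)` -- with the default
#' `coefficient = 1` this is exactly `reference / smoothed`, i.e. the signal
#' is increased in direct proportion to the fractional decrease of the
#' reference.  Since the reference is expected only ever to *increase*
#' outside dim episodes (S-phase doubling), a monotonically increasing
#' reference yields no correction at all, and all correction factors are
#' >= 1.
#'
#' @param gfp numeric signal series (e.g. nuclear GFP means).
#' @param redNuclearMean numeric reference series, same length (>= 3),
#'   strictly positive.
#' @param coefficient proportionality coefficient (default 1).
#' @param smoothWindow moving-average window for the reference (default 3).
#' @param requireGfpDecrease if `TRUE`, only frames in which the smoothed
#'   signal itself decreased are corrected (off by default; the simultaneous
#'   signal decrease is a soft criterion).
#' @return A list with `raw`, `corrected`, `factor` (per-frame multipliers,
#'   all >= 1) and `reference` (the running reference level).
#' @export
focusCorrection <- function(gfp, redNuclearMean, coefficient = 1,
                            smoothWindow = 3L, requireGfpDecrease = FALSE) {
  n <- length(gfp)
  if (n != length(redNuclearMean) || n < 3L)
    stop("gfp and red series must have equal length >= 3")
  if (any(redNuclearMean <= 0))
    stop("reference intensities must be strictly positive")
  s <- .movingAverage(redNuclearMean, smoothWindow)
  ref <- numeric(n)
  ref[1L] <- s[1L]
  for (i in 2:n) ref[i] <- if (s[i] >= ref[i - 1L]) s[i] else ref[i - 1L]
  factor <- ifelse(s < ref, 1 + coefficient * (ref / s - 1), 1)
  if (requireGfpDecrease) {
    gs <- .movingAverage(gfp, smoothWindow)
    dec <- c(FALSE, diff(gs) < 0)
    factor[!dec] <- 1
  }
  list(raw = gfp, corrected = gfp * factor, factor = factor, reference = ref)
}

# Centered moving average; ends use the partial in-bounds window.
.movingAverage <- function(x, window = 3L) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Tidy per-cell per-frame feature table
#'
#' One row per cell-frame: morphology from the tracked masks, and -- when
#' fluorescence channels are supplied -- the nuclear signal (brightest-25\%
#' mean and Gaussian fit) from `gfp`, the reference nuclear mean from
#' `red`, and the focus-corrected nuclear signal.
#'
#' @param result a [TrackingResult-class].
#' @param gfp optional [FluorMovie-class] (signal channel).
#' @param red optional [FluorMovie-class] (constant nuclear reference).
#' @param pad pixels of context around each mask when cropping fluorescence
#'   windows (default 5).
#' @param coefficient focus-correction coefficient (default 1).
#' @return A data.frame with columns `cell_id`, `frame`, `area`,
#'   `major_axis`, `minor_axis`, `circumference`, `centroid_row`,
#'   `centroid_col`, and when fluorescence is given `nuclear_mean`,
#'   `gauss_amplitude`, `gauss_sigma_row`, `gauss_sigma_col`,
#'   `gauss_offset`, `red_nuclear_mean`, `corrected_nuclear_mean`.
#' @export
extractFeatures <- function(result, gfp = NULL, red = NULL, pad = 5L,
                            coefficient = 1) {
  stopifnot(is(result, "TrackingResult"))
  rows <- list()
  for (tr in result@tracks) {
    d <- tr@frameDim
    cellRows <- list()
    for (k in seq_along(tr@frames)) {
      f <- tr@frames[k]
      mask <- matrix(FALSE, d[1L], d[2L])
      mask[tr@maskIdx[[k]]] <- TRUE
      mo <- morphology(mask)
      row <- data.frame(cell_id = tr@cellId, frame = f, area = mo$area,
                        major_axis = mo$majorAxis, minor_axis = mo$minorAxis,
                        circumference = mo$circumference,
                        centroid_row = mo$centroid[1L],
                        centroid_col = mo$centroid[2L])
      if (!is.null(gfp)) {
        bb <- .maskBBox(mask)
        r1 <- max(1L, bb[1L] - pad); r2 <- min(d[1L], bb[2L] + pad)
        c1 <- max(1L, bb[3L] - pad); c2 <- min(d[2L], bb[4L] + pad)
        mWin <- mask[r1:r2, c1:c2, drop = FALSE]
        ns <- nuclearSignal(getFrame(gfp, f)[r1:r2, c1:c2, drop = FALSE],
                            mWin)
        row$nuclear_mean <- ns$nuclearMean
        g <- ns$gaussian
        row$gauss_amplitude <- if (is.null(g)) NA_real_ else g[["amplitude"]]
        row$gauss_sigma_row <- if (is.null(g)) NA_real_ else g[["sigmaRow"]]
        row$gauss_sigma_col <- if (is.null(g)) NA_real_ else g[["sigmaCol"]]
        row$gauss_offset <- if (is.null(g)) NA_real_ else g[["offset"]]
        if (!is.null(red)) {
          nsr <- nuclearSignal(getFrame(red, f)[r1:r2, c1:c2, drop = FALSE],
                               mWin)
          row$red_nuclear_mean <- nsr$nuclearMean
        }
      }
      cellRows[[k]] <- row
    }
    if (!length(cellRows)) next
    df <- do.call(rbind, cellRows)
    if (!is.null(gfp) && !is.null(red) && nrow(df) >= 3L) {
      ord <- order(df$frame)  # chronological for the correction
      fc <- focusCorrection(df$nuclear_mean[ord], df$red_nuclear_mean[ord],
                            coefficient = coefficient)
      df$corrected_nuclear_mean[ord] <- fc$corrected
    } else if (!is.null(gfp) && !is.null(red)) {
      df$corrected_nuclear_mean <- df$nuclear_mean
    }
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
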