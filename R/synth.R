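# Synthetic phase-contrast colony movies with full ground truth.  The
# generator renders exactly the structure the tracking algorithm assumes:
# dark elliptical cell interiors ringed by 2-px bright halos on a mid-gray
# background, slow exponential growth, occasional buds appearing at the
# mother boundary, sub-pixel frame-to-frame jitter, and two fluorescence
# channels (a translocating nuclear signal and a constant nuclear reference
# with focus-drift dimming episodes).

#' Construct synthetic colony parameters
#'
#' Defaults define the generator's standard study conditions; see
#' [ColonyParams-class] for the meaning of each field.
#'
#' @param nInitialCells,nFrames,frameShape colony geometry.
#' @param interiorIntensity,haloIntensity,backgroundIntensity 8-bit levels.
#' @param noiseSd Gaussian pixel noise SD.
#' @param growthRate fractional area growth per frame.
#' @param budProbability per eligible cell per frame.
#' @param jitterSd per-frame centre jitter, pixels.
#' @param shmooFraction fraction of founders with a shmoo protrusion.
#' @param budInitialArea bud area at birth, pixels.
#' @param rngSeed integer seed.
#' @return A [ColonyParams-class] object.
#' @export
colonyParams <- function(nInitialCells = 20, nFrames = 50,
                         frameShape = c(320, 320), interiorIntensity = 40,
                         haloIntensity = 230, backgroundIntensity = 150,
                         noiseSd = 6, growthRate = 0.01,
                         budProbability = 0.01, jitterSd = 0.3,
                         shmooFraction = 0, budInitialArea = 140,
                         rngSeed = 1) {
  new("ColonyParams", nInitialCells = nInitialCells, nFrames = nFrames,
      frameShape = frameShape, interiorIntensity = interiorIntensity,
      haloIntensity = haloIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      growthRate = growthRate, budProbability = budProbability,
      jitterSd = jitterSd, shmooFraction = shmooFraction,
      budInitialArea = budInitialArea, rngSeed = rngSeed)
}

# Ellipse membership for pixel centres in a bounding window.
# Returns which() indices into the full frame.
.ellipseIdx <- function(d, cr, cc, a, b, phi) {
  r1 <- max(1L, floor(cr - a)); r2 <- min(d[1L], ceiling(cr + a))
  c1 <- max(1L, floor(cc - a)); c2 <- min(d[2L], ceiling(cc + a))
  if (r1 > r2 || c1 > c2) return(integer(0))
  rs <- r1:r2; cs <- c1:c2
  dr <- outer(rs - cr, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - cc)
  u <- (dr * cos(phi) + dc * sin(phi)) / a
  v <- (-dr * sin(phi) + dc * cos(phi)) / b
  inside <- u * u + v * v <= 1
  w <- which(inside, arr.ind = TRUE)
  (cs[w[, 2L]] - 1L) * d[1L] + rs[w[, 1L]]
}

#' Generate a synthetic colony movie with ground truth
#'
#' Simulates a colony forward in time and renders phase, GFP-like and
#' red-reference channels plus per-frame truth label images, the lineage,
#' nucleus parameters and focus-dimming episodes.  Fully deterministic
#' given `rngSeed`.  Founders that cannot be placed without collisions
#' raise an error suggesting a larger frame.
#'
#' @param params a [ColonyParams-class].
#' @return A list with elements `phase` ([PhaseMovie-class]), `gfp`, `red`
#'   ([FluorMovie-class]) and `truth` ([GroundTruth-class]).
#' @export
generateColony <- function(params = colonyParams()) {
  stopifnot(is(params, "ColonyParams"))
  validObject(params)
  .withSeed(params@rngSeed, .generateColonyImpl(params))
}

.generateColonyImpl <- function(p) {
  d <- as.integer(p@frameShape)
  nF <- as.integer(p@nFrames)
  nC0 <- as.integer(p@nInitialCells)
  growF <- (1 + p@growthRate)^(nF / 2)  # radius-safety factor for spacing

  # --- founders ---------------------------------------------------------
  founders <- list()
  margin <- 26
  for (i in seq_len(nC0)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      r0 <- stats::runif(1, margin, d[1L] - margin)
      c0 <- stats::runif(1, margin, d[2L] - margin)
      area <- stats::runif(1, 530, 800)
      rad <- sqrt(area / pi)
      ok <- TRUE
      for (f2 in founders) {
        lim <- growF * (rad + f2$rad) + 12
        if (sqrt((r0 - f2$r)^2 + (c0 - f2$c)^2) < lim) { ok <- FALSE; break }
      }
      if (ok) {
        founders[[i]] <- list(r = r0, c = c0, rad = rad, area = area)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", nC0, " founder cells without collisions; ",
           "use a larger frameShape or fewer cells")
  }

  # --- cell state table -------------------------------------------------
  nShmoo <- round(p@shmooFraction * nC0)
  cells <- data.frame(
    id = seq_len(nC0),
    motherId = NA_integer_,
    birthFrame = 1L,
    r = vapply(founders, `[[`, numeric(1), "r"),
    c = vapply(founders, `[[`, numeric(1), "c"),
    area = vapply(founders, `[[`, numeric(1), "area"),
    aspect = stats::runif(nC0, 1.0, 1.25),
    phi = stats::runif(nC0, 0, pi),
    budAngle = NA_real_,
    shmoo = seq_len(nC0) <= nShmoo,
    g1Len = 4L + stats::rgeom(nC0, 0.15),
    gfpAmp = stats::runif(nC0, 250, 400),
    redAmp = stats::runif(nC0, 300, 500),
    sigma = stats::runif(nC0, 2.2, 2.8))

  # focus-dimming episodes of the red channel, one per affected cell
  mkEpisode <- function(id) {
    if (nF < 8L || stats::runif(1) > 0.3) return(NULL)
    start <- sample(2:(nF - 5L), 1L)
    len <- sample(4:8, 1L)
    data.frame(id = id, start = start, end = min(nF, start + len - 1L),
               dimFraction = stats::runif(1, 0.15, 0.35))
  }
  episodes <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(seq_len(nC0), mkEpisode)))
  if (is.null(episodes))
    episodes <- data.frame(id = integer(0), start = integer(0),
                           end = integer(0), dimFraction = numeric(0))

  phaseFrames <- vector("list", nF)
  gfpFrames <- vector("list", nF)
  redFrames <- vector("list", nF)
  labelFrames <- vector("list", nF)
  nucRows <- list()

  maxSemi <- function(area, aspect) sqrt(area * aspect / pi)

  for (f in seq_len(nF)) {
    if (f > 1L) {
      # growth and jitter
      cells$area <- cells$area * (1 + p@growthRate)
      nAlive <- nrow(cells)
      cells$r <- cells$r + stats::rnorm(nAlive, 0, p@jitterSd)
      cells$c <- cells$c + stats::rnorm(nAlive, 0, p@jitterSd)
      # buds ride on the mother boundary, pushed outward as both grow
      for (k in which(!is.na(cells$motherId))) {
        m <- match(cells$motherId[k], cells$id)
        dist <- maxSemi(cells$area[m], cells$aspect[m]) +
          maxSemi(cells$area[k], cells$aspect[k]) + 3
        cells$r[k] <- cells$r[m] + dist * sin(cells$budAngle[k])
        cells$c[k] <- cells$c[m] + dist * cos(cells$budAngle[k])
      }
      # budding: only mature, established cells bud
      eligible <- which(cells$area > 450 & (f - cells$birthFrame) > 10)
      for (m in eligible) {
        if (stats::runif(1) >= p@budProbability) next
        if (f > nF - 3L) next  # a bud needs a few frames to be seedable
        ang <- stats::runif(1, 0, 2 * pi)
        budArea <- p@budInitialArea
        budRad <- sqrt(budArea / pi)
        dist <- maxSemi(cells$area[m], cells$aspect[m]) + budRad + 3
        br <- cells$r[m] + dist * sin(ang)
        bc <- cells$c[m] + dist * cos(ang)
        if (br < 16 || br > d[1L] - 16 || bc < 16 || bc > d[2L] - 16) next
        clash <- FALSE
        for (k in seq_len(nrow(cells))) {
          if (k == m) next
          lim <- growF * (maxSemi(cells$area[k], cells$aspect[k]) + budRad) + 9
          if (sqrt((br - cells$r[k])^2 + (bc - cells$c[k])^2) < lim) {
            clash <- TRUE; break
          }
        }
        if (clash) next
        newId <- max(cells$id) + 1L
        cells <- rbind(cells, data.frame(
          id = newId, motherId = cells$id[m], birthFrame = f,
          r = br, c = bc, area = budArea,
          aspect = stats::runif(1, 1.0, 1.15), phi = ang,
          budAngle = ang, shmoo = FALSE,
          g1Len = 4L + stats::rgeom(1, 0.15),
          gfpAmp = stats::runif(1, 250, 400),
          redAmp = stats::runif(1, 300, 500),
          sigma = stats::runif(1, 2.2, 2.8)))
      }
    }

    # --- render ownership (truth labels) --------------------------------
    own <- matrix(0L, d[1L], d[2L])
    bestD <- matrix(Inf, d[1L], d[2L])
    geom <- list()
    for (k in seq_len(nrow(cells))) {
      a <- maxSemi(cells$area[k], cells$aspect[k])
      b <- sqrt(cells$area[k] / (pi * cells$aspect[k]))
      idx <- .ellipseIdx(d, cells$r[k], cells$c[k], a, b, cells$phi[k])
      if (cells$shmoo[k]) {
        # teardrop protrusion along the orientation axis
        pr <- cells$r[k] + 0.9 * a * sin(cells$phi[k])
        pc <- cells$c[k] + 0.9 * a * cos(cells$phi[k])
        idx <- union(idx, .ellipseIdx(d, pr, pc, 0.6 * a, 0.45 * b,
                                      cells$phi[k]))
      }
      geom[[k]] <- list(a = a, b = b, idx = idx)
      if (!length(idx)) next
      rr <- (idx - 1L) %% d[1L] + 1L
      cc <- (idx - 1L) %/% d[1L] + 1L
      dd <- (rr - cells$r[k])^2 + (cc - cells$c[k])^2
      take <- dd < bestD[idx]
      own[idx[take]] <- cells$id[k]
      bestD[idx[take]] <- dd[take]
    }

    # --- phase ----------------------------------------------------------
    ph <- matrix(p@backgroundIntensity, d[1L], d[2L])
    ph[own > 0L] <- p@interiorIntensity
    for (k in seq_len(nrow(cells))) {
      g <- geom[[k]]
      ring <- setdiff(.ellipseIdx(d, cells$r[k], cells$c[k],
                                  g$a + 2, g$b + 2, cells$phi[k]), g$idx)
      ring <- ring[own[ring] == 0L]
      ph[ring] <- pmax(ph[ring], p@haloIntensity)
    }
    if (p@noiseSd > 0)
      ph <- ph + stats::rnorm(length(ph), 0, p@noiseSd)
    ph <- matrix(as.integer(pmin(pmax(floor(ph + 0.5), 0), 255)),
                 d[1L], d[2L])

    # --- fluorescence ---------------------------------------------------
    gfp <- matrix(20, d[1L], d[2L])
    red <- matrix(15, d[1L], d[2L])
    gfp[own > 0L] <- 60
    red[own > 0L] <- 30
    for (k in seq_len(nrow(cells))) {
      age <- f - cells$birthFrame[k]
      inG1 <- age <= cells$g1Len[k]
      nr0 <- cells$r[k] + stats::rnorm(1, 0, 0.7)
      nc0 <- cells$c[k] + stats::rnorm(1, 0, 0.7)
      dim <- 1
      ep <- episodes[episodes$id == cells$id[k], , drop = FALSE]
      if (nrow(ep) && f >= ep$start[1L] && f <= ep$end[1L])
        dim <- 1 - ep$dimFraction[1L]
      gAmp <- if (inG1) cells$gfpAmp[k] * dim else 0
      rAmp <- cells$redAmp[k] * dim
      s <- cells$sigma[k]
      h <- ceiling(3.5 * s)
      r1 <- max(1L, floor(nr0 - h)); r2 <- min(d[1L], ceiling(nr0 + h))
      c1 <- max(1L, floor(nc0 - h)); c2 <- min(d[2L], ceiling(nc0 + h))
      if (r1 <= r2 && c1 <= c2) {
        rs <- r1:r2; cs <- c1:c2
        gsub <- exp(-(outer((rs - nr0)^2, (cs - nc0)^2, `+`)) / (2 * s^2))
        gfp[rs, cs] <- gfp[rs, cs] + gAmp * gsub
        red[rs, cs] <- red[rs, cs] + rAmp * gsub
      }
      nucRows[[length(nucRows) + 1L]] <- data.frame(
        frame = f, id = cells$id[k], centerRow = nr0, centerCol = nc0,
        gfpAmplitude = gAmp, redAmplitude = rAmp, sigma = s)
    }
    if (p@noiseSd > 0) {
      gfp <- pmax(gfp + stats::rnorm(length(gfp), 0, 5), 0)
      red <- pmax(red + stats::rnorm(length(red), 0, 5), 0)
    }

    phaseFrames[[f]] <- ph
    gfpFrames[[f]] <- gfp
    redFrames[[f]] <- red
    labelFrames[[f]] <- own
  }

  truth <- new("GroundTruth", labelMovie = labelFrames,
               lineage = cells[, c("id", "birthFrame", "motherId")],
               nuclei = do.call(rbind, nucRows),
               focusEpisodes = episodes)
  list(phase = phaseMovie(phaseFrames, frameInterval = 3),
       gfp = fluorMovie(gfpFrames, "gfp"),
       red = fluorMovie(redFrames, "red"),
       truth = truth)
}

#' Seed label image from ground truth
#'
#' Takes the truth labels at one frame and renumbers them left to right via
#' [finalizeSeed()], producing the seed a user would have drawn on that
#' frame.  The mapping from the new seed labels back to the truth cell ids
#' is attached as attribute `"truthIds"` on the returned label matrix.
#'
#' @param truth a [GroundTruth-class].
#' @param frameIndex frame to seed from (default: last frame).
#' @return A [SeedLabelImage-class].
#' @export
truthToSeed <- function(truth, frameIndex = length(truth@labelMovie)) {
  stopifnot(is(truth, "GroundTruth"))
  if (frameIndex < 1L || frameIndex > length(truth@labelMovie))
    stop("frameIndex out of range")
  L <- truth@labelMovie[[frameIndex]]
  out <- finalizeSeed(seedLabelImage(L))
  # recover which truth id each new label corresponds to (max overlap)
  ids <- sort(setdiff(unique(as.vector(out@labels)), 0L))
  truthIds <- vapply(ids, function(k) {
    v <- L[out@labels == k]
    v <- v[v > 0L]
    if (!length(v)) return(NA_integer_)
    as.integer(names(which.max(table(v))))
  }, integer(1))
  attr(out@labels, "truthIds") <- truthIds
  out
}
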