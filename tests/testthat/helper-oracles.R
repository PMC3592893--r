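# Independent brute-force oracles and small shape builders used across the
# suite.  The oracles deliberately re-derive results from first principles
# (exhaustive distance minimization, literal flooding, literal per-threshold
# recomputation) rather than calling the code paths they check.

# Solid disc mask.
disc <- function(nr, nc, cr, cc, r) {
  x <- matrix(FALSE, nr, nc)
  x[(row(x) - cr)^2 + (col(x) - cc)^2 <= r^2] <- TRUE
  x
}

# Render a phase-contrast-like cell: dark disc, 2-px halo ring, gray
# background, optional Gaussian noise.
renderCell <- function(nr, nc, cr, cc, r, interior = 40, halo = 230,
                       background = 150, noiseSd = 0) {
  ph <- matrix(background, nr, nc)
  inside <- disc(nr, nc, cr, cc, r)
  ring <- disc(nr, nc, cr, cc, r + 2) & !inside
  ph[ring] <- halo
  ph[inside] <- interior
  if (noiseSd > 0) ph <- ph + rnorm(nr * nc, 0, noiseSd)
  ph <- matrix(as.integer(pmin(pmax(floor(ph + 0.5), 0), 255)), nr, nc)
  ph
}

segWindow <- function(phase, seed) {
  storage.mode(phase) <- "integer"
  new("SegWindow", origin = c(1L, 1L), phase = phase, seedMask = seed)
}

# Exhaustive squared Euclidean distance to the nearest FALSE pixel.
oracleEdtSq <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(bg) == 0L) return(matrix(1e15, nr, nc))
  d <- matrix(0, nr, nc)
  for (i in which(mask)) {
    r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
    d[i] <- min((bg[, 1L] - r)^2 + (bg[, 2L] - c)^2)
  }
  d
}

# Literal re-implementation of the watershed definition: regional-maxima
# plateaus of the exhaustive distance transform seed the basins (numbered by
# row-major first pixel), flooding proceeds from deep to shallow with
# first-in-first-out tie-breaking and row-major push order.
oracleWatershed <- function(cand) {
  nr <- nrow(cand); nc <- ncol(cand)
  lab <- matrix(0L, nr, nc)
  if (!any(cand)) return(lab)
  d <- oracleEdtSq(cand)
  dr8 <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc8 <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  seen <- matrix(FALSE, nr, nc)
  nextLab <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!cand[r, c] || seen[r, c]) next
    h <- d[r, c]; isMax <- TRUE
    stack <- list(c(r, c)); seen[r, c] <- TRUE; members <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      members[[length(members) + 1L]] <- p
      for (k in 1:8) {
        qr <- p[1L] + dr8[k]; qc <- p[2L] + dc8[k]
        if (qr < 1L || qr > nr || qc < 1L || qc > nc || !cand[qr, qc]) next
        if (d[qr, qc] > h) isMax <- FALSE
        else if (d[qr, qc] == h && !seen[qr, qc]) {
          seen[qr, qc] <- TRUE
          stack[[length(stack) + 1L]] <- c(qr, qc)
        }
      }
    }
    if (isMax) {
      nextLab <- nextLab + 1L
      for (p in members) lab[p[1L], p[2L]] <- nextLab
    }
  }
  # flood
  qd <- numeric(0); qseq <- numeric(0); qlab <- integer(0)
  qr_ <- integer(0); qc_ <- integer(0); alive <- logical(0)
  sq <- 0
  push <- function(r, c, L) {
    qd[length(qd) + 1L] <<- d[r, c]
    sq <<- sq + 1
    qseq[length(qseq) + 1L] <<- sq
    qlab[length(qlab) + 1L] <<- L
    qr_[length(qr_) + 1L] <<- r
    qc_[length(qc_) + 1L] <<- c
    alive[length(alive) + 1L] <<- TRUE
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] == 0L) next
    for (k in 1:8) {
      qr <- r + dr8[k]; qc <- c + dc8[k]
      if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
      if (cand[qr, qc] && lab[qr, qc] == 0L) push(qr, qc, lab[r, c])
    }
  }
  while (any(alive)) {
    idx <- which(alive)
    mx <- max(qd[idx])
    sel <- idx[qd[idx] == mx]
    e <- sel[which.min(qseq[sel])]
    alive[e] <- FALSE
    r <- qr_[e]; c <- qc_[e]
    if (lab[r, c] != 0L) next
    lab[r, c] <- qlab[e]
    for (k in 1:8) {
      qr <- r + dr8[k]; qc <- c + dc8[k]
      if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
      if (cand[qr, qc] && lab[qr, qc] == 0L) push(qr, qc, lab[r, c])
    }
  }
  lab
}

# Independent per-threshold recomputation of the composite: binarize,
# watershed, score every sub-region by the three criteria (vectorized,
# re-implemented here), and sum the accepted regions over all 256 passes.
oracleComposite <- function(phase, seed, cfg = trackConfig()) {
  nr <- nrow(phase); nc <- ncol(phase)
  total <- matrix(0, nr, nc)
  for (t in 1:256) {
    cand <- phase < t
    if (!any(cand)) next
    lab <- watershedSubregions(cand)
    n <- max(lab)
    pos <- lab > 0L
    areas <- tabulate(lab[pos], nbins = n)
    ov <- tabulate(lab[pos & seed], nbins = n)
    nonc <- tabulate(lab[pos & !cand], nbins = n)
    borderLabs <- setdiff(unique(c(lab[1L, ], lab[nr, ], lab[, 1L],
                                   lab[, nc])), 0L)
    keep <- (ov / areas > cfg@seedOverlapMin) &
            (nonc / areas < cfg@noncellMax) &
            !(seq_len(n) %in% borderLabs)
    acc <- matrix(FALSE, nr, nc)
    acc[pos] <- keep[lab[pos]]
    total <- total + acc
  }
  total
}

# Tiny synthetic colony used by several test files (cheap to track).
smallColony <- function(rngSeed = 7, nCells = 3, nFrames = 6,
                        shape = c(170, 170), ...) {
  generateColony(colonyParams(nInitialCells = nCells, nFrames = nFrames,
                              frameShape = shape, rngSeed = rngSeed, ...))
}
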