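# Small pixel-level helpers shared across modules.  The package-wide
# conventions: matrices are (row, col) with row 1 at the image top, masks are
# logical matrices, connectivity is 8-connected unless stated otherwise.

#' Euclidean distance transform
#'
#' Exact Euclidean distance from every pixel to the nearest `FALSE` pixel of
#' `mask` (so pixels that are already `FALSE` get 0).  Used both to build the
#' watershed topography of a candidate mask and, applied to the complement of
#' a seed, to compute the movement penalty.
#'
#' @param mask logical matrix.
#' @return Numeric matrix of distances in pixels.
#' @export
distanceTransform <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  .edtCpp(mask)
}

#' 8-connected component labelling
#'
#' @param mask logical matrix.
#' @return Integer matrix; components numbered by the row-major order of
#'   their first pixel, background 0.
#' @export
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  .label8Cpp(mask)
}

# Bounding box of a mask as c(r1, r2, c1, c2); NULL for an empty mask.
.maskBBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  c(min(w[, 1L]), max(w[, 1L]), min(w[, 2L]), max(w[, 2L]))
}

# 3x3 box dilation / erosion with FALSE outside the image.
.dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out | p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  out
}

.erode3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    out <- out & p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  out
}

# Morphological closing with a 3x3 box.
.close3 <- function(m) .erode3(.dilate3(m))

# Fill background regions fully enclosed by the mask (i.e. background
# components that do not touch the image border).
.fillHoles <- function(m) {
  bg <- !m
  lab <- .label8Cpp(bg)
  if (max(lab) == 0L) return(m)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  hole <- lab > 0L & !(lab %in% border)
  m | hole
}

# Restore-on-exit RNG scoping so generator functions are deterministic
# without clobbering the caller's random stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
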