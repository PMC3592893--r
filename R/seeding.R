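# Seeding: produce the labeled seed image for the first segmented time
# point (usually the movie's last frame) and clean it up for tracking.

#' Watershed seeding of a single frame
#'
#' Pixels below `threshold` form the foreground, which is partitioned by
#' the same distance-transform watershed used throughout the package
#' ([watershedSubregions()]).  Regions smaller than `minArea` pixels are
#' discarded and the survivors labeled in watershed order.  An empty
#' foreground yields an empty label image with a warning, not an error.
#'
#' @param frame 8-bit integer matrix.
#' @param threshold intensity threshold in [0, 255].
#' @param minArea minimal region area in pixels (default 10).
#' @return A [SeedLabelImage-class].
#' @export
seedWatershed <- function(frame, threshold, minArea = 10) {
  stopifnot(is.matrix(frame))
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255)
    stop("threshold must lie in [0, 255]")
  fg <- frame < threshold
  if (!any(fg)) {
    warning("threshold ", threshold, " yields an empty foreground")
    return(seedLabelImage(matrix(0L, nrow(frame), ncol(frame))))
  }
  lab <- watershedSubregions(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minArea)
  out <- matrix(0L, nrow(frame), ncol(frame))
  newId <- integer(max(lab))
  newId[keep] <- seq_along(keep)
  pos <- lab > 0L
  out[pos] <- newId[lab[pos]]
  seedLabelImage(out)
}

#' Apply a merge/remove edit script to a seed label image
#'
#' The scriptable surrogate for interactive seed correction: `merge(a, b)`
#' unions two labels' pixels under the smaller of the two ids, and
#' `remove(k)` deletes a label's pixels to background.  Replay is a pure
#' function of the initial labels.  Labels referenced must exist at the
#' time each command applies; a stale reference is an error naming the
#' offending command index.  Note that merged/removed ids leave gaps in the
#' numbering until [finalizeSeed()] renumbers.
#'
#' @param labels a [SeedLabelImage-class].
#' @param script data.frame with columns `op` (`"merge"` or `"remove"`),
#'   `labelA` and (for merge) `labelB`.
#' @return The edited [SeedLabelImage-class].
#' @export
applyEdits <- function(labels, script) {
  stopifnot(is(labels, "SeedLabelImage"), is.data.frame(script))
  L <- labels@labels
  if (nrow(script) == 0L) return(labels)
  if (!all(c("op", "labelA") %in% names(script)))
    stop("script needs columns op, labelA (and labelB for merges)")
  for (i in seq_len(nrow(script))) {
    op <- as.character(script$op[i])
    a <- as.integer(script$labelA[i])
    if (!a %in% L)
      stop(sprintf("edit %d: label %d does not exist", i, a))
    if (op == "remove") {
      L[L == a] <- 0L
    } else if (op == "merge") {
      b <- as.integer(script$labelB[i])
      if (!b %in% L)
        stop(sprintf("edit %d: label %d does not exist", i, b))
      keep <- min(a, b); drop <- max(a, b)
      L[L == drop] <- keep
    } else {
      stop(sprintf("edit %d: unknown op '%s'", i, op))
    }
  }
  seedLabelImage(L)
}

#' Finalize a seed label image
#'
#' Per label: background holes fully enclosed by the label are filled and
#' one-pixel background "cracks" are closed (morphological 3x3 closing,
#' restricted so that no pixel of another label is claimed and only current
#' background pixels are added).  Labels are then renumbered 1..N from left
#' to right by ascending region centroid column (ties by ascending centroid
#' row).  The operation is idempotent on its own output.
#'
#' @param labels a [SeedLabelImage-class].
#' @return The finalized [SeedLabelImage-class] with consecutive labels.
#' @export
finalizeSeed <- function(labels) {
  stopifnot(is(labels, "SeedLabelImage"))
  L <- labels@labels
  ids <- sort(setdiff(unique(as.vector(L)), 0L))
  for (id in ids) {
    m <- L == id
    filled <- .fillHoles(m)
    closed <- .close3(filled) | filled
    add <- closed & (L == 0L)
    L[add] <- id
  }
  # left-to-right renumbering
  ids <- sort(setdiff(unique(as.vector(L)), 0L))
  if (length(ids)) {
    cents <- t(vapply(ids, function(id) {
      w <- which(L == id, arr.ind = TRUE)
      c(mean(w[, 2L]), mean(w[, 1L]))  # (col, row)
    }, numeric(2)))
    ord <- order(cents[, 1L], cents[, 2L])
    out <- matrix(0L, nrow(L), ncol(L))
    for (k in seq_along(ord)) out[L == ids[ord[k]]] <- k
    L <- out
  }
  seedLabelImage(L)
}

#' Read a seed edit script from CSV
#'
#' CSV columns: `op`, `label_a`, `label_b` (empty for removes).
#'
#' @param path CSV path.
#' @return data.frame suitable for [applyEdits()].
#' @export
readEditScript <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  data.frame(op = x$op, labelA = x$label_a,
             labelB = if ("label_b" %in% names(x)) x$label_b else NA)
}
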