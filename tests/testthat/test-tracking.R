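# Backward tracking driver and termination rules.

test_that("termination rules fire on size bounds and growth jumps", {
  cfg <- trackConfig()  # minArea 10
  prev <- disc(30, 30, 15, 15, 6)     # 113 px
  mk <- function(n) { m <- matrix(FALSE, 30, 30); m[seq_len(n)] <- TRUE; m }
  expect_identical(checkTermination(mk(8), prev, cfg, maxArea = 400),
                   "too_small")
  expect_identical(checkTermination(mk(250), prev, cfg, maxArea = 200),
                   "too_large")
  # 1.6x the predecessor (within the area cap) is a growth jump
  prev100 <- mk(100)
  expect_identical(checkTermination(mk(160), prev100, cfg, maxArea = 1000),
                   "growth_jump")
  # equal size continues
  expect_identical(checkTermination(prev, prev, cfg, maxArea = 400),
                   "continue")
  # exactly 1.5x is not "more than 50%"
  expect_identical(checkTermination(mk(150), prev100, cfg, maxArea = 1000),
                   "continue")
})

test_that("a static synthetic cell is tracked through every frame", {
  syn <- smallColony(rngSeed = 2, nCells = 1, nFrames = 10,
                     shape = c(90, 90), growthRate = 0, jitterSd = 0,
                     budProbability = 0)
  truthMask <- truthLabels(syn$truth)[[10]] == 1L
  tr <- trackCell(syn$phase, truthMask, cellId = 1L)
  expect_identical(terminationReason(tr), "reached_first_frame")
  expect_null(disappearanceFrame(tr))
  expect_identical(trackFrames(tr), as.integer(10:1))
  for (f in 1:10) {
    m <- maskAt(tr, f)
    tm <- truthLabels(syn$truth)[[f]] == 1L
    iou <- sum(m & tm) / sum(m | tm)
    expect_gte(iou, 0.9)
  }
})

test_that("a degenerate single-frame request segments just that frame", {
  syn <- smallColony(rngSeed = 4, nCells = 1, nFrames = 3, shape = c(90, 90),
                     budProbability = 0)
  seed <- truthLabels(syn$truth)[[3]] == 1L
  tr <- trackCell(syn$phase, seed, firstFrame = 3, lastFrame = 3)
  expect_identical(trackFrames(tr), 3L)
  expect_true(any(maskAt(tr, 3)))
})

test_that("tracking rejects bad seeds", {
  syn <- smallColony(rngSeed = 4, nCells = 1, nFrames = 3, shape = c(90, 90))
  expect_error(trackCell(syn$phase, matrix(FALSE, 90, 90)), "empty")
  expect_error(trackCell(syn$phase, matrix(TRUE, 50, 50)), "shape")
})

test_that("tracking is deterministic and independent of cell order", {
  syn <- smallColony(rngSeed = 7)
  seeds <- truthToSeed(syn$truth, 6)
  r1 <- trackAll(syn$phase, seeds)
  r2 <- trackAll(syn$phase, seeds)
  expect_identical(lapply(tracks(r1), function(t) t@maskIdx),
                   lapply(tracks(r2), function(t) t@maskIdx))

  # cells are segmented one by one against their own seeds: running them
  # individually in reverse order reproduces every track bit-exactly
  L <- labelMatrix(seeds)
  ids <- sort(setdiff(unique(as.vector(L)), 0L))
  maxArea <- trackConfig()@maxAreaFactor *
    max(vapply(ids, function(i) sum(L == i), numeric(1)))
  solo <- lapply(rev(ids), function(i)
    trackCell(syn$phase, L == i, cellId = i, maxArea = maxArea))
  solo <- solo[order(vapply(solo, cellId, integer(1)))]
  expect_identical(lapply(solo, function(t) t@maskIdx),
                   lapply(tracks(r1), function(t) t@maskIdx))
})

test_that("tracked areas shrink backward in time within the growth guard", {
  syn <- smallColony(rngSeed = 9)
  seeds <- truthToSeed(syn$truth, 6)
  res <- trackAll(syn$phase, seeds)
  for (tr in tracks(res)) {
    areas <- vapply(tr@maskIdx, length, integer(1))  # descending frames
    # going backward, no mask exceeds 1.5x its successor
    if (length(areas) > 1L)
      expect_true(all(areas[-1] <= 1.5 * areas[-length(areas)]))
  }
})

test_that("whole-track survival compounds geometrically", {
  expect_identical(compoundingSuccess(0.99, 100), 0.99^100)
  expect_equal(compoundingSuccess(0.99, 100), 0.366, tolerance = 1e-3)
  expect_identical(compoundingSuccess(1, 500), 1)
  expect_identical(compoundingSuccess(0.5, 0), 1)
})

test_that("a removed seed label leaves the other tracks unaffected", {
  syn <- smallColony(rngSeed = 7)
  seeds <- truthToSeed(syn$truth, 6)
  full <- trackAll(syn$phase, seeds)
  edited <- applyEdits(seeds, data.frame(op = "remove", labelA = 2L))
  part <- trackAll(syn$phase, edited)
  expect_identical(vapply(tracks(part), cellId, integer(1)),
                   setdiff(vapply(tracks(full), cellId, integer(1)), 2L))
  for (tr in tracks(part)) {
    ref <- tracks(full)[[which(vapply(tracks(full), cellId, integer(1)) ==
                                 cellId(tr))]]
    expect_identical(tr@maskIdx, ref@maskIdx)
  }
})
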