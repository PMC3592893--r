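# The voting core: binarization, watershed partition, region scoring and
# the 256-threshold composite sweep.

test_that("binarization is strict-below and rejects out-of-range thresholds", {
  u <- matrix(100L, 5, 5)
  expect_false(any(binarizeAtThreshold(u, 50)))
  expect_false(any(binarizeAtThreshold(u, 100)))
  expect_true(all(binarizeAtThreshold(u, 101)))
  expect_true(all(binarizeAtThreshold(u, 256)))
  expect_error(binarizeAtThreshold(u, 0), "1, 256")
  expect_error(binarizeAtThreshold(u, 257), "1, 256")
})

test_that("candidate masks are nested in the threshold", {
  set.seed(42)
  for (i in 1:50) {
    img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    for (t in sample(1:255, 20)) {
      a <- binarizeAtThreshold(img, t)
      b <- binarizeAtThreshold(img, t + 1)
      expect_true(all(b[a]))  # a subset of b
    }
  }
})

test_that("watershed partitions candidates and splits necks", {
  # single solid disc: one basin covering the disc
  d1 <- disc(25, 25, 13, 13, 8)
  ws <- watershedSubregions(d1)
  expect_identical(max(ws), 1L)
  expect_identical(ws > 0, d1)

  # two discs joined by a thin neck: two basins meeting inside the neck
  cand <- disc(30, 50, 15, 13, 8) | disc(30, 50, 15, 37, 8)
  cand[15, 14:36] <- TRUE
  ws <- watershedSubregions(cand)
  expect_identical(max(ws), 2L)
  expect_identical(ws > 0, cand)
  boundaryCols <- range(which(ws == 1, arr.ind = TRUE)[, 2])[2]
  expect_gt(boundaryCols, 21)   # split lies strictly inside the neck
  expect_lt(boundaryCols, 30)

  # empty mask: zero sub-regions
  expect_identical(max(watershedSubregions(matrix(FALSE, 5, 5))), 0L)
})

test_that("watershed matches the brute-force flooding oracle", {
  cases <- list(disc(18, 18, 9, 9, 6))
  neck <- disc(22, 34, 11, 9, 6) | disc(22, 34, 11, 25, 6)
  neck[11, 10:24] <- TRUE
  cases <- c(cases, list(neck))
  set.seed(11)
  for (i in 1:6) {
    m <- matrix(runif(20 * 20) < 0.55, 20, 20)
    cases <- c(cases, list(m))
  }
  for (cand in cases)
    expect_identical(watershedSubregions(cand), oracleWatershed(cand))
})

test_that("distance transform matches exhaustive minimization", {
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(runif(15 * 17) < 0.6, 15, 17)
    expect_equal(distanceTransform(m), sqrt(oracleEdtSq(m)), tolerance = 1e-12)
  }
  expect_equal(distanceTransform(matrix(FALSE, 4, 4)), matrix(0, 4, 4))
})

test_that("sub-region scoring applies the three acceptance criteria", {
  cfg <- trackConfig()
  n <- 12
  full <- matrix(TRUE, n, n)
  interior <- matrix(FALSE, n, n); interior[4:8, 4:8] <- TRUE

  # all criteria trivially met
  expect_identical(scoreSubregion(interior, interior, full, cfg), 1L)

  # one pixel on the window border kills the region
  border <- interior; border[1, 5] <- TRUE
  expect_identical(scoreSubregion(border, full, full, cfg), 0L)

  # 50% seed overlap passes (i) but 40% non-candidate area fails (ii)
  region <- matrix(FALSE, n, n); region[4:8, 4:7] <- TRUE  # 20 px
  seed <- matrix(FALSE, n, n); seed[4:8, 4:5] <- TRUE      # overlap 10/20
  cand <- full; cand[4:5, 4:7] <- FALSE                    # 8/20 non-cand
  expect_identical(scoreSubregion(region, seed, cand, cfg), 0L)
  # same region with full candidate support passes
  expect_identical(scoreSubregion(region, seed, full, cfg), 1L)

  # exactly 40% overlap is not "more than 40%"
  seed2 <- matrix(FALSE, n, n); seed2[4:8, 4] <- TRUE; seed2[4:6, 5] <- TRUE
  expect_identical(sum(region & seed2) / sum(region), 0.4)
  expect_identical(scoreSubregion(region, seed2, full, cfg), 0L)

  expect_error(scoreSubregion(matrix(FALSE, n, n), seed, full, cfg),
               "non-empty")
})

test_that("a uniform window yields an all-zero composite", {
  ph <- matrix(100L, 30, 30)
  seed <- disc(30, 30, 15, 15, 5)
  cs <- compositeSweep(segWindow(ph, seed))
  expect_identical(scoreStage(cs), "raw")
  expect_identical(cs@nThresholds, 256L)
  expect_true(all(scores(cs) == 0))
})

test_that("composite sweep equals the per-threshold oracle on a cell window", {
  set.seed(3)
  ph <- renderCell(40, 40, 20, 20, 9, noiseSd = 6)
  seed <- disc(40, 40, 20, 20, 9)
  cfg <- trackConfig()
  cs <- compositeSweep(segWindow(ph, seed), cfg)
  expect_identical(scores(cs), oracleComposite(ph, seed, cfg))
  s <- scores(cs)
  expect_true(all(s >= 0 & s <= 256))
  expect_true(all(s == round(s)))
  # the disc interior collects votes, the far background none
  expect_gt(s[20, 20], 100)
  expect_identical(s[3, 3], 0)
})

test_that("empty seeds are rejected by the window invariant", {
  expect_error(new("SegWindow", origin = c(1L, 1L),
                   phase = matrix(0L, 5, 5),
                   seedMask = matrix(FALSE, 5, 5)),
               "non-empty")
})

test_that("enlarging the seed never lowers raw composite votes", {
  set.seed(9)
  ph <- renderCell(36, 36, 18, 18, 8, noiseSd = 4)
  small <- disc(36, 36, 18, 18, 5)
  big <- disc(36, 36, 18, 18, 8)   # superset of small
  cfg <- trackConfig()
  s1 <- scores(compositeSweep(segWindow(ph, small), cfg))
  s2 <- scores(compositeSweep(segWindow(ph, big), cfg))
  expect_true(all(s2 >= s1))
})
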