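# Morphology, nuclear signal extraction and focus correction.

test_that("morphology of elementary shapes", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 4:13] <- TRUE
  mo <- morphology(sq)
  expect_identical(mo$area, 100L)
  expect_equal(mo$centroid, c(10.5, 8.5))
  expect_equal(mo$majorAxis, mo$minorAxis)
  expect_equal(mo$circumference, 36)  # 4 * (10 - 1) contour steps

  d <- disc(31, 31, 16, 16, 10)
  mo <- morphology(d)
  expect_equal(mo$area, 100 * pi, tolerance = 0.05)
  expect_equal(mo$majorAxis, 20, tolerance = 0.05)
  expect_equal(mo$minorAxis, 20, tolerance = 0.05)

  ln <- matrix(FALSE, 5, 60); ln[3, 6:55] <- TRUE
  mo <- morphology(ln)
  expect_identical(mo$area, 50L)
  expect_gt(mo$majorAxis / max(mo$minorAxis, 1e-9), 20)

  expect_error(morphology(matrix(FALSE, 3, 3)), "empty")
})

test_that("morphology is translation invariant and axes swap on rotation", {
  set.seed(14)
  base <- disc(40, 40, 15, 15, 7) | disc(40, 40, 15, 22, 5)
  m1 <- morphology(base)
  shifted <- matrix(FALSE, 40, 40)
  w <- which(base, arr.ind = TRUE)
  shifted[cbind(w[, 1] + 8, w[, 2] + 5)] <- TRUE
  m2 <- morphology(shifted)
  expect_identical(m2$area, m1$area)
  expect_equal(m2$majorAxis, m1$majorAxis)
  expect_equal(m2$minorAxis, m1$minorAxis)
  expect_equal(m2$circumference, m1$circumference)
  expect_equal(m2$centroid, m1$centroid + c(8, 5))

  rot <- t(base)[, rev(seq_len(40))]  # 90-degree rotation
  m3 <- morphology(rot)
  expect_equal(m3$majorAxis, m1$majorAxis)
  expect_equal(m3$minorAxis, m1$minorAxis)
})

plantNucleus <- function(nr, nc, cr, cc, amp, sigma, offset, noiseSd = 2) {
  g <- offset + amp * exp(-((row(matrix(0, nr, nc)) - cr)^2 +
                            (col(matrix(0, nr, nc)) - cc)^2) / (2 * sigma^2))
  g + matrix(rnorm(nr * nc, 0, noiseSd), nr, nc)
}

test_that("nuclear signal recovers a planted Gaussian", {
  set.seed(8)
  cell <- disc(31, 31, 16, 16, 12)
  fl <- plantNucleus(31, 31, 14, 18, amp = 500, sigma = 2.5, offset = 50)
  ns <- nuclearSignal(fl, cell)
  expect_true(cell[ns$peak[1], ns$peak[2]])
  expect_equal(ns$peak[1], 14, tolerance = 1.01)
  expect_equal(ns$peak[2], 18, tolerance = 1.01)
  expect_identical(ns$nucleusArea, as.integer(round(0.25 * sum(cell))))
  expect_false(is.null(ns$gaussian))
  expect_equal(unname(ns$gaussian["amplitude"]), 500, tolerance = 0.1)
  expect_lt(abs(ns$gaussian["centerRow"] - 14), 1)
  expect_lt(abs(ns$gaussian["centerCol"] - 18), 1)
})

test_that("uniform fluorescence still defines a 25% nucleus", {
  cell <- disc(21, 21, 11, 11, 8)
  fl <- matrix(75, 21, 21)
  ns <- nuclearSignal(fl, cell)
  expect_identical(ns$nucleusArea, as.integer(round(0.25 * sum(cell))))
  expect_identical(sum(ns$nucleusMask), ns$nucleusArea)
  expect_true(all(cell[ns$nucleusMask]))  # nucleus lies inside the cell
  expect_equal(ns$nuclearMean, 75)
  if (!is.null(ns$gaussian))
    expect_lt(ns$gaussian["amplitude"], 1e-3)
})

test_that("the peak stays inside the cell even for an edge nucleus", {
  set.seed(15)
  cell <- disc(25, 25, 13, 13, 7)
  fl <- plantNucleus(25, 25, 13, 21, amp = 300, sigma = 2, offset = 20)
  ns <- nuclearSignal(fl, cell)
  expect_true(cell[ns$peak[1], ns$peak[2]])
})

test_that("gaussian fit parameter recovery over many random nuclei", {
  set.seed(1234)
  ampErr <- centErr <- numeric(50)
  for (i in 1:50) {
    amp <- runif(1, 150, 600)
    sg <- runif(1, 1.6, 3.2)
    cr <- runif(1, 12, 18); cc <- runif(1, 12, 18)
    cell <- disc(29, 29, 15, 15, 11)
    fl <- plantNucleus(29, 29, cr, cc, amp, sg, offset = runif(1, 20, 80),
                       noiseSd = 4)
    ns <- nuclearSignal(fl, cell)
    if (is.null(ns$gaussian)) { ampErr[i] <- Inf; centErr[i] <- Inf; next }
    ampErr[i] <- abs(ns$gaussian["amplitude"] - amp) / amp
    centErr[i] <- sqrt((ns$gaussian["centerRow"] - cr)^2 +
                       (ns$gaussian["centerCol"] - cc)^2)
  }
  expect_lt(median(ampErr), 0.10)
  expect_lt(median(centErr), 1)
})

test_that("focus correction boosts dips in direct proportion", {
  gfp <- rep(200, 25)
  red <- rep(1000, 25)
  red[11:15] <- 800  # a flat 20% dip
  fc <- focusCorrection(gfp, red)
  # interior dip frames see the full smoothed 20% decrease -> exactly x1.25
  expect_equal(fc$corrected[12:14], gfp[12:14] * 1.25, tolerance = 1e-9)
  expect_true(all(fc$factor >= 1))
  expect_equal(fc$corrected[1:9], gfp[1:9])

  # constant reference: identity
  fc0 <- focusCorrection(gfp, rep(1000, 25))
  expect_identical(fc0$corrected, gfp)
  expect_true(all(fc0$factor == 1))

  # monotonically increasing reference (S-phase-like): no correction
  fc1 <- focusCorrection(gfp, seq(500, 1500, length.out = 25))
  expect_identical(fc1$corrected, gfp)

  expect_error(focusCorrection(gfp, c(rep(1000, 24), 0)), "positive")
  expect_error(focusCorrection(1:2, 1:2), "length")
})

test_that("the feature table ties morphology and fluorescence together", {
  syn <- smallColony(rngSeed = 5, nCells = 2, nFrames = 5, shape = c(150, 150),
                     budProbability = 0)
  seeds <- truthToSeed(syn$truth, 5)
  res <- trackAll(syn$phase, seeds)
  ft <- extractFeatures(res, gfp = syn$gfp, red = syn$red)
  expect_true(all(c("cell_id", "frame", "area", "major_axis", "minor_axis",
                    "circumference", "centroid_row", "centroid_col",
                    "nuclear_mean", "gauss_amplitude",
                    "red_nuclear_mean", "corrected_nuclear_mean") %in%
                    names(ft)))
  expect_identical(nrow(ft), sum(vapply(tracks(res), function(t)
    length(t@frames), integer(1))))
  expect_true(all(ft$area >= trackConfig()@minArea))
  expect_true(all(ft$major_axis >= ft$minor_axis))
  expect_true(all(ft$corrected_nuclear_mean >= ft$nuclear_mean - 1e-9))
})
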