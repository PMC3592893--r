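# Composite refinement: penalties, dual thresholding, growth guard and the
# connectivity filter.

rawScore <- function(m) new("CompositeScore", scores = m, stage = "raw",
                            nThresholds = 256L)

test_that("distance penalty subtracts the distance to the seed", {
  s <- matrix(200, 11, 11)
  seed <- matrix(FALSE, 11, 11); seed[6, 6] <- TRUE
  dp <- distancePenalty(rawScore(s), seed)
  expect_identical(scoreStage(dp), "distance_penalized")
  expect_identical(scores(dp)[6, 6], 200)        # inside the seed: unchanged
  expect_identical(scores(dp)[9, 10], 200 - 5)   # exactly 5 px away (3,4)
  expect_identical(scores(dp)[6, 11], 200 - 5)

  z <- distancePenalty(rawScore(matrix(0, 11, 11)), seed)
  d <- distanceTransform(!seed)
  expect_true(all(scores(z) <= 0))
  expect_identical(scores(z), -d)
})

test_that("phase penalty subtracts the rescaled phase image", {
  s <- matrix(100, 4, 4)
  ph <- matrix(200L, 4, 4)
  seed <- matrix(TRUE, 4, 4)
  dp <- distancePenalty(rawScore(s), seed)
  expect_identical(scores(phasePenalty(dp, ph, trackConfig())),
                   matrix(100 - 0.25 * 200, 4, 4))
  cfg0 <- trackConfig(phasePenaltyWeight = 0)
  expect_identical(scores(phasePenalty(dp, ph, cfg0)), scores(dp))
})

test_that("stage transitions are enforced", {
  s <- rawScore(matrix(1, 3, 3))
  seed <- matrix(TRUE, 3, 3)
  ph <- matrix(0L, 3, 3)
  expect_error(phasePenalty(s, ph), "distance-penalized")
  dp <- distancePenalty(s, seed)
  expect_error(distancePenalty(dp, seed), "raw")
  expect_error(dualThreshold(dp, seed), "phase-penalized")
})

test_that("penalties never increase any score", {
  set.seed(21)
  for (i in 1:10) {
    s <- matrix(sample(0:256, 100, replace = TRUE), 10, 10)
    seed <- disc(10, 10, sample(3:8, 1), sample(3:8, 1), 2)
    ph <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    dp <- distancePenalty(rawScore(s), seed)
    expect_true(all(scores(dp) <= s))
    expect_true(all(scores(dp)[seed] == s[seed]))
    pp <- phasePenalty(dp, ph)
    expect_true(all(scores(pp) <= scores(dp)))
  }
})

ppScore <- function(m) new("CompositeScore", scores = m,
                           stage = "phase_penalized", nThresholds = 256L)

test_that("dual thresholding keeps seed pixels permissively, new pixels strictly", {
  # 80 low pixels and 20 high pixels put the 90th percentile at 100
  s <- matrix(0, 10, 10)
  s[, 9:10] <- 100
  seed <- matrix(FALSE, 10, 10)
  s[1, 1] <- 35; seed[1, 1] <- TRUE   # 0.35 P, in seed -> condition (i)
  s[2, 1] <- 35                       # 0.35 P, not in seed -> excluded
  s[3, 1] <- 90                       # 0.90 P, not in seed -> condition (ii)
  put <- dualThreshold(ppScore(s), seed, trackConfig())
  expect_false(put$rethresholded)
  expect_true(put$mask[1, 1])
  expect_false(put$mask[2, 1])
  expect_true(put$mask[3, 1])
  expect_true(all(put$mask[, 9:10]))
})

test_that("dual-threshold masks shrink as the fractions grow", {
  set.seed(33)
  for (i in 1:10) {
    s <- matrix(rnorm(144, 50, 60), 12, 12)
    seed <- disc(12, 12, 6, 6, 3)
    lo <- runif(1, 0.1, 0.5)
    delta <- runif(1, 0.05, 0.3)
    a <- dualThreshold(ppScore(s), seed, trackConfig(lowFraction = lo))
    b <- dualThreshold(ppScore(s), seed, trackConfig(lowFraction = lo),
                       bump = delta)
    expect_true(all(a$mask[b$mask]))  # bumped mask is a subset
  }
})

test_that("a non-positive percentile yields an empty mask with a warning", {
  s <- matrix(-5, 8, 8)
  seed <- disc(8, 8, 4, 4, 2)
  expect_warning(put <- dualThreshold(ppScore(s), seed), "degenerate")
  expect_false(any(put$mask))
})

test_that("the growth guard re-thresholds once and only once", {
  # 100-px window with 11 pixels at 100 puts the 90th percentile at exactly
  # 100.  The 9-px seed scores 100, a 16-px ring around it scores 55: the
  # ring passes the base high threshold (0.5 P = 50) but not the bumped one
  # (0.7 P = 70), so the guard's one-time bump strips it.
  s <- matrix(0, 10, 10)
  seed <- matrix(FALSE, 10, 10); seed[5:7, 5:7] <- TRUE
  s[seed] <- 100
  ring <- matrix(FALSE, 10, 10); ring[4:8, 4:8] <- TRUE; ring <- ring & !seed
  s[ring] <- 55
  s[1, 10] <- 100; s[2, 10] <- 100
  cfg <- trackConfig(lowFraction = 0.3, highFraction = 0.5)
  put <- dualThreshold(ppScore(s), seed, cfg)
  expect_identical(sum(put$mask), 27L)  # seed + ring + two stray 100s
  expect_gt(sum(put$mask), (1 + cfg@growthFraction) * sum(seed))
  g1 <- growthGuard(put, seed, ppScore(s), cfg)
  expect_true(g1$rethresholded)
  expect_identical(sum(g1$mask), 11L)   # the ring is gone
  # still above the growth tolerance, but the bump applies only once
  expect_gt(sum(g1$mask), (1 + cfg@growthFraction) * sum(seed))
  expect_identical(growthGuard(g1, seed, ppScore(s), cfg), g1)
  # no growth relative to a full-window seed -> untouched
  all10 <- matrix(TRUE, 10, 10)
  small <- dualThreshold(ppScore(s), all10, cfg)
  expect_identical(growthGuard(small, all10, ppScore(s), cfg), small)
})

test_that("largest component filtering keeps one deterministic object", {
  m <- matrix(FALSE, 20, 20)
  m[2:11, 2:13] <- TRUE          # 120 px
  m[15:16, 15:17] <- TRUE        # 6 px
  out <- largestComponent(m)
  expect_identical(out, { x <- matrix(FALSE, 20, 20); x[2:11, 2:13] <- TRUE; x })

  one <- disc(15, 15, 8, 8, 4)
  expect_identical(largestComponent(one), one)

  # two equal components: the one whose first pixel comes first row-major
  eq <- matrix(FALSE, 10, 10)
  eq[2:3, 2:3] <- TRUE
  eq[6:7, 6:7] <- TRUE
  out <- largestComponent(eq)
  expect_true(all(out[2:3, 2:3]))
  expect_false(any(out[6:7, 6:7]))

  expect_false(any(largestComponent(matrix(FALSE, 5, 5))))
})
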