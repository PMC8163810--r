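test_that("labelGaps uses 8-connectivity and respects nodata", {
  # two pixels touching only diagonally form one gap of size 2
  v <- matrix(25, 4, 4)
  v[1, 1] <- 1; v[2, 2] <- 1
  lm <- labelGaps(heightRaster(v, resolution = 1.25), 2)
  expect_identical(gapSizes(lm), 2L)
  # all-canopy raster has zero gaps
  expect_identical(gapSizes(labelGaps(uniformCHM(25), 2)), integer(0))
  # nodata pixels are never gap pixels
  v[3, 3] <- NA
  lm2 <- labelGaps(heightRaster(v, resolution = 1.25), 2)
  expect_identical(sum(gapSizes(lm2)), 2L)
  # idempotent on relabeling: sizes multiset is stable
  expect_identical(sort(gapSizes(labelGaps(heightRaster(v, 1.25), 2))),
                   sort(gapSizes(lm2)))
})

test_that("labelGaps matches a brute-force flood fill on random rasters", {
  set.seed(71)
  for (i in 1:30) {
    mask <- matrix(runif(400) < 0.35, 20, 20)
    chm <- heightRaster(ifelse(mask, 1, 25) + 0, resolution = 1.25)
    sizes <- gapSizes(labelGaps(chm, 2))
    oracle <- floodFillLabels(mask)
    oSizes <- if (max(oracle) > 0) tabulate(oracle[oracle > 0]) else integer(0)
    expect_identical(length(sizes), max(oracle))
    expect_identical(sort(sizes), sort(as.integer(oSizes)))
  }
})

test_that("edge gaps can be excluded on request", {
  v <- matrix(25, 5, 5)
  v[1, 1:2] <- 1          # touches the edge
  v[3, 3] <- 1            # interior
  chm <- heightRaster(v, resolution = 1.25)
  expect_identical(sort(gapSizes(labelGaps(chm, 2))), c(1L, 2L))
  expect_identical(gapSizes(labelGaps(chm, 2, dropEdgeGaps = TRUE)), 1L)
})

test_that("gapAreaByThreshold reports nested, correctly scaled areas", {
  v <- matrix(25, 10, 10)
  v[1:2, 1:5] <- 1        # 10-pixel gap
  v[8, 8] <- 6            # mid-height pixel, a gap only at threshold >= 6
  chm <- heightRaster(v, resolution = 1.25)
  tab <- gapAreaByThreshold(chm, thresholds = c(2, 8))
  expect_equal(tab$total_area_m2[1], 10 * 1.5625)
  expect_gte(tab$total_area_m2[2], tab$total_area_m2[1])
  expect_equal(tab$pct_of_study_area[1], 100 * 10 / 100)
  expect_error(gapAreaByThreshold(chm, thresholds = c(8, 2)), "ascending")
  # a pre/post pair built to exactly double the gap area reports ratio 2
  v2 <- v
  v2[9:10, 1:5] <- 1      # duplicate the gap mask in a disjoint region
  v2[8, 8] <- 25
  post <- heightRaster(v2, resolution = 1.25)
  tabPre <- gapAreaByThreshold(chm, thresholds = 8)
  tabPost <- gapAreaByThreshold(post, thresholds = 8)
  expect_equal(tabPost$total_area_m2 /
                 (tabPre$total_area_m2 - 1.5625), 2)  # minus the 6 m pixel
})

test_that("zetaLogPMF matches closed forms and normalizes", {
  # zeta(2) = pi^2/6
  expect_equal(zetaLogPMF(1, 2), log(6 / pi^2), tolerance = 1e-12)
  # pmf ratios cancel the normalizer
  for (lam in c(1.2, 2, 3.7))
    expect_equal(zetaLogPMF(2, lam) - zetaLogPMF(1, lam), -lam * log(2),
                 tolerance = 1e-12)
  # truncated-series normalization with a tail bound at lam = 2:
  # sum_{k>K} k^-2 < 1/K, so the partial sum to 1e7 is within 1e-4 of 1
  k <- seq_len(1e7)
  expect_lt(abs(sum(exp(zetaLogPMF(k, 2))) - 1), 1e-4)
  expect_error(zetaLogPMF(1, 1), "lambda")
  expect_error(zetaLogPMF(0, 2), "k must be")
})

test_that("estimateLambda bookkeeping is exact", {
  sizes <- sampleZeta(50, 2, seed = 1L)
  post <- estimateLambda(sizes, nTotal = 20000L, nBurnin = 5000L,
                         thin = 25L, seed = 2L)
  expect_identical(length(posteriorChain(post)), (20000L - 5000L) %/% 25L)
  expect_true(all(posteriorChain(post) >= 1.01 &
                    posteriorChain(post) <= 5))
  cri <- credibleInterval(post)
  expect_lte(cri[1], lambdaMedian(post))
  expect_gte(cri[2], lambdaMedian(post))
  # determinism
  post2 <- estimateLambda(sizes, nTotal = 20000L, nBurnin = 5000L,
                          thin = 25L, seed = 2L)
  expect_identical(posteriorChain(post2), posteriorChain(post))
  expect_error(estimateLambda(integer(0)), "at least one")
  expect_error(estimateLambda(c(1L, 0L)), ">= 1 pixel")
  expect_error(estimateLambda(sizes, nTotal = 10001L), "multiple of thin")
})

test_that("the posterior concentrates correctly in edge cases", {
  # all sizes k = 1: the likelihood increases with the exponent, so the
  # posterior piles at the upper prior bound
  post1 <- estimateLambda(rep(1L, 400), nTotal = 20000L, nBurnin = 5000L,
                          thin = 25L, seed = 3L)
  expect_gt(lambdaMedian(post1), 4.5)
  # recovery at moderate n
  sizes <- sampleZeta(2000, 2, seed = 4L)
  post2 <- estimateLambda(sizes, nTotal = 20000L, nBurnin = 5000L,
                          thin = 25L, seed = 5L)
  expect_lt(abs(lambdaMedian(post2) - 2), 0.1)
})

test_that("MH posterior median agrees with the grid-posterior oracle", {
  for (s in 1:3) {
    sizes <- sampleZeta(400, 1.6 + 0.4 * s, seed = 100L + s)
    post <- estimateLambda(sizes, nTotal = 20000L, nBurnin = 5000L,
                           thin = 25L, seed = 200L + s)
    expect_lt(abs(lambdaMedian(post) - gridPosteriorMedian(sizes)), 0.02)
  }
})

test_that("compareLambda flags separated posteriors and not overlapping ones", {
  fast <- function(sizes, seed) estimateLambda(sizes, nTotal = 20000L,
                                               nBurnin = 5000L, thin = 25L,
                                               seed = seed)
  pA <- fast(sampleZeta(1500, 2.4, seed = 301L), 1L)
  pB <- fast(sampleZeta(1500, 1.8, seed = 302L), 2L)
  cmp <- compareLambda(pA, pB)
  expect_true(cmp$significant)
  expect_lt(cmp$deltaMedian, 0)
  # identical posteriors: no significance, zero median difference
  cmpSame <- compareLambda(pA, pA)
  expect_false(cmpSame$significant)
  expect_equal(cmpSame$deltaMedian, 0)
  # small-n case with overlapping intervals is not significant
  pC <- fast(sampleZeta(200, 2.0, seed = 303L), 3L)
  pD <- fast(sampleZeta(200, 2.05, seed = 304L), 4L)
  expect_false(compareLambda(pC, pD)$significant)
})

test_that("credible intervals cover the true exponent across replicates", {
  covered <- 0L
  for (s in 1:20) {
    sizes <- sampleZeta(1000, 2, seed = 400L + s)
    post <- estimateLambda(sizes, nTotal = 20000L, nBurnin = 5000L,
                           thin = 25L, seed = 500L + s)
    cri <- credibleInterval(post)
    if (cri[1] <= 2 && 2 <= cri[2]) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})
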