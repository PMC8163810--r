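test_that("buildTransitionMatrix bins paired pixels correctly", {
  # identity dynamics: diagonal counts
  r5 <- heightRaster(matrix(4.5, 3, 3), resolution = 5)
  m <- buildTransitionMatrix(r5, r5)
  expect_equal(m@counts[5, 5], 9)
  expect_equal(sum(m@counts), 9)
  # direct binning: 3.2 -> 7.9 and 7.9 -> 3.2
  pre <- heightRaster(matrix(c(3.2, 7.9), 1, 2), resolution = 5)
  post <- heightRaster(matrix(c(7.9, 3.2), 1, 2), resolution = 5)
  m2 <- buildTransitionMatrix(pre, post)
  expect_identical(m2@nClasses, 8L)
  expect_equal(m2@counts[8, 4], 1)
  expect_equal(m2@counts[4, 8], 1)
  expect_equal(sum(m2@counts), 2)
  # heights exactly at the top edge fall in the last class
  pre3 <- heightRaster(matrix(c(8, 1), 1, 2), resolution = 5)
  m3 <- buildTransitionMatrix(pre3, pre3)
  expect_equal(m3@counts[8, 8], 1)
  # column sums equal per-class start counts from a brute-force histogram
  set.seed(81)
  h0 <- matrix(runif(400, 0, 20), 20, 20)
  h1 <- pmax(h0 + rnorm(400, 0, 3), 0)
  mB <- buildTransitionMatrix(heightRaster(h0, resolution = 5),
                              heightRaster(h1, resolution = 5))
  startCounts <- tabulate(pmin(floor(h0) + 1, mB@nClasses),
                          nbins = mB@nClasses)
  expect_equal(unname(colSums(mB@counts)), as.numeric(startCounts))
  expect_error(buildTransitionMatrix(pre, heightRaster(matrix(1, 2, 2),
                                                       resolution = 5)),
               "identical grid")
})

test_that("steadyState matches closed forms and the power-iteration oracle", {
  mk <- function(P, n = 1000) new("TransitionModel", counts = round(P * n),
                                  classWidth = 1,
                                  nClasses = nrow(P),
                                  edges = 0:nrow(P))
  # 2x2 closed form: stationary of [[0.9,0.2],[0.1,0.8]] is (2/3, 1/3)
  ss <- steadyState(mk(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)))
  expect_equal(stationaryDistribution(ss), c(2, 1) / 3, tolerance = 1e-12)
  # doubly symmetric matrix: uniform stationary distribution
  ss2 <- steadyState(mk(matrix(0.5, 2, 2)))
  expect_equal(stationaryDistribution(ss2), c(0.5, 0.5), tolerance = 1e-12)
  # mean height uses class midpoints
  expect_equal(meanCanopyHeight(ss), 2 / 3 * 0.5 + 1 / 3 * 1.5)
  expect_equal(meanCanopyHeight(steadyState(mk(matrix(c(0.9, 0.1, 0.2, 0.8),
                                                      2, 2)),
                                            meanFrom = "edge")), 1 / 3)
  # oracle equivalence on random irreducible matrices up to 54 classes;
  # the oracle iterates exactly the column-normalized count matrix
  set.seed(91)
  for (i in 1:10) {
    n <- sample(2:54, 1)
    counts <- round(randomStochasticMatrix(n) * 1e6)
    m <- new("TransitionModel", counts = counts, classWidth = 1,
             nClasses = n, edges = 0:n)
    Pn <- sweep(counts, 2, colSums(counts), "/")
    got <- stationaryDistribution(steadyState(m))
    expect_lt(sum(abs(got - powerIterationStationary(Pn))), 1e-10)
  }
})

test_that("steadyState enforces stochasticity and irreducibility diagnostics", {
  # two closed classes: error names the blocks
  P <- diag(2)
  m <- new("TransitionModel", counts = P * 10, classWidth = 1,
           nClasses = 2L, edges = 0:2)
  expect_error(steadyState(m), "reducible")
  # empty start class gets a uniform column with a warning
  counts <- matrix(c(5, 5, 0, 0), 2, 2)
  m2 <- new("TransitionModel", counts = counts, classWidth = 1,
            nClasses = 2L, edges = 0:2)
  expect_warning(ss <- steadyState(m2), "empty start class")
  expect_equal(sum(stationaryDistribution(ss)), 1, tolerance = 1e-12)
})

test_that("stationarity invariant holds for the reported distribution", {
  set.seed(101)
  counts <- round(randomStochasticMatrix(20) * 1e5)
  m <- new("TransitionModel", counts = counts, classWidth = 1,
           nClasses = 20L, edges = 0:20)
  x <- stationaryDistribution(steadyState(m))
  Pn <- sweep(counts, 2, colSums(counts), "/")
  expect_lt(sum(abs(as.vector(Pn %*% x) - x)), 1e-10)
  # column normalization is exact
  expect_true(all(abs(colSums(Pn) - 1) < 1e-12))
})

test_that("steadyStatePosterior concentrates and stays deterministic", {
  set.seed(111)
  P <- randomStochasticMatrix(6)
  mk <- function(scale) new("TransitionModel", counts = round(P * scale),
                            classWidth = 1, nClasses = 6L, edges = 0:6)
  # envelope width decreases monotonically with count scale
  widths <- vapply(c(1e2, 1e4, 1e6), function(sc) {
    ss <- steadyStatePosterior(mk(sc), nDraws = 1500L, seed = 7L)
    mean(ss@envHigh - ss@envLow)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # huge counts collapse the envelope onto the point estimate
  ssBig <- steadyStatePosterior(mk(1e6), nDraws = 1500L, seed = 8L)
  expect_lt(max(ssBig@envHigh - ssBig@envLow), 0.01)
  expect_true(all(ssBig@envLow <= stationaryDistribution(ssBig) + 1e-6))
  expect_true(all(ssBig@envHigh >= stationaryDistribution(ssBig) - 1e-6))
  # determinism under a fixed seed
  s1 <- steadyStatePosterior(mk(100), nDraws = 400L, seed = 9L)
  s2 <- steadyStatePosterior(mk(100), nDraws = 400L, seed = 9L)
  expect_identical(s1@envLow, s2@envLow)
  expect_identical(credibleInterval(s1), credibleInterval(s2))
})

test_that("an all-zero count matrix yields the uniform equilibrium", {
  # with no observations every column is the uniform prior, whose point
  # estimate (uniform columns) has the uniform stationary distribution
  m <- new("TransitionModel", counts = matrix(0, 4, 4), classWidth = 1,
           nClasses = 4L, edges = 0:4)
  expect_warning(ss <- steadyState(m), "empty start class")
  expect_equal(stationaryDistribution(ss), rep(0.25, 4), tolerance = 1e-12)
})

test_that("compareDistributions measures departure from equilibrium", {
  set.seed(121)
  P <- randomStochasticMatrix(8)
  m <- new("TransitionModel", counts = round(P * 500), classWidth = 1,
           nClasses = 8L, edges = 0:8)
  ss <- steadyStatePosterior(m, nDraws = 800L, seed = 3L)
  # projected vs itself: no distance, no departure
  selfCmp <- compareDistributions(stationaryDistribution(ss), ss)
  expect_equal(selfCmp$tvDistance, 0, tolerance = 1e-12)
  expect_equal(selfCmp$meanDiff, 0, tolerance = 1e-9)
  # translating the observed distribution up one class makes the projected
  # mean sit exactly 1 m below the observed mean
  proj <- new("SteadyState", distribution = c(0.2, 0.3, 0.5, rep(0, 5)),
              meanHeight = sum(c(0.2, 0.3, 0.5) * c(0.5, 1.5, 2.5)),
              envLow = numeric(0), envHigh = numeric(0),
              meanHeightCI = numeric(0), nDraws = 0L, seed = NA_integer_,
              edges = 0:8)
  obsUp <- c(0, 0.2, 0.3, 0.5, rep(0, 4))
  expect_equal(compareDistributions(obsUp, proj)$meanDiff, -1,
               tolerance = 1e-12)
  # a blowdown pair projects an equilibrium below the pre-disturbance mean
  chm <- generateCHM(syntheticForestConfig(extentM = 150, seed = 19L))
  blow <- applyBlowdown(chm, 0.25, seed = 20L)
  tchPre <- aggregateMean(chm, 4L)     # 5 m grid
  tchPost <- aggregateMean(blow$chm, 4L)
  mB <- buildTransitionMatrix(
    heightRaster(gridValues(tchPre), resolution = 5),
    heightRaster(gridValues(tchPost), resolution = 5))
  ssB <- suppressWarnings(steadyStatePosterior(mB, nDraws = 600L, seed = 4L))
  obs <- heightDistribution(heightRaster(gridValues(tchPre), resolution = 5),
                            mB@nClasses)
  cmpB <- compareDistributions(obs, ssB)
  expect_lt(cmpB$meanProjected, cmpB$meanObserved)
  expect_error(compareDistributions(c(0.5, 0.5), ssB), "class grid")
})
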