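test_that("fitAllometry recovers exact and noisy power laws", {
  # exact linear case a = 10, b = 1
  plots <- data.frame(tch_m = c(10, 20, 30), agbd_mg_ha = c(100, 200, 300))
  fit <- fitAllometry(plots)
  expect_lt(abs(fit@a / 10 - 1), 1e-8)
  expect_lt(abs(fit@b / 1 - 1), 1e-8)
  expect_equal(fit@r2, 1, tolerance = 1e-12)
  # residual-SSE-zero recovery for a curved law generated by the simulator
  fit2 <- fitAllometry(generatePlots(allometrySimConfig(
    aTrue = 2.5, bTrue = 1.6, residualSd = 0, tchRange = c(10, 35),
    seed = 3L)))
  expect_lt(sum((fit2@plotData$agbd_mg_ha -
                   fit2@a * fit2@plotData$tch_m^fit2@b)^2), 1e-12)
  # degenerate inputs error
  expect_error(fitAllometry(plots[1:2, ]), "3 plots")
  expect_error(fitAllometry(data.frame(tch_m = c(10, 10, 10),
                                       agbd_mg_ha = c(1, 2, 3))), "distinct")
  expect_error(fitAllometry(data.frame(tch_m = c(10, 20, 30),
                                       agbd_mg_ha = c(5, 5, 5))), "variance")
})

test_that("parameter recovery is stable across noisy replicates", {
  # 18 plots at a realistic residual sd: median |b error| < 0.15 and the
  # fitted curve explains noise-free evaluation data almost perfectly
  bErr <- r2Eval <- numeric(20)
  tchEval <- seq(12, 32, length.out = 50)
  truthEval <- 3.8 * tchEval^1.27
  for (s in 1:20) {
    fit <- fitAllometry(generatePlots(allometrySimConfig(seed = s)))
    bErr[s] <- abs(fit@b - 1.27)
    predEval <- fit@a * tchEval^fit@b
    r2Eval[s] <- 1 - sum((truthEval - predEval)^2) /
      sum((truthEval - mean(truthEval))^2)
  }
  expect_lt(median(bErr), 0.15)
  expect_gt(median(r2Eval), 0.99)
})

test_that("predictAGBD applies the power model cell-wise", {
  fit <- fitAllometry(data.frame(tch_m = c(10, 20, 30),
                                 agbd_mg_ha = c(100, 200, 300)))
  r <- gridLayer(matrix(c(20, 0, NA, 5), 2, 2), resolution = 70)
  pred <- predictAGBD(fit, r)
  expect_equal(gridValues(pred)[1, 1], 200, tolerance = 1e-6)
  expect_equal(gridValues(pred)[2, 1], 0)            # TCH 0 -> 0
  expect_true(is.na(gridValues(pred)[1, 2]))         # nodata propagates
  # scalar-loop oracle on a random raster
  set.seed(7)
  v <- matrix(runif(36, 5, 30), 6, 6)
  vr <- gridLayer(v, resolution = 70)
  oracle <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) oracle[i, j] <- fit@a * v[i, j]^fit@b
  expect_equal(gridValues(predictAGBD(fit, vr)), oracle, tolerance = 1e-12)
})

test_that("agbdToACD scales linearly and preserves ordering", {
  expect_equal(agbdToACD(100), 47)
  expect_equal(agbdToACD(0), 0)
  x <- c(10, 50, 200)
  expect_equal(agbdToACD(x) / 0.47, x)               # round trip
  expect_true(all(diff(agbdToACD(x)) > 0))           # monotone
  expect_equal(agbdToACD(2 * x), 2 * agbdToACD(x))   # linear
  expect_error(agbdToACD(-1), ">= 0")
})

test_that("monteCarloACD handles degenerate noise and is deterministic", {
  fit0 <- fitAllometry(generatePlots(allometrySimConfig(
    residualSd = 0, seed = 4L)))
  cells <- gridLayer(matrix(seq(12, 30, length.out = 9), 3, 3),
                     resolution = 70)
  m <- monteCarloACD(fit0, cells, nDraws = 50L, seed = 1L)
  # sigma = 0: bounds collapse onto the central estimate
  expect_equal(m@ciLow, gridValues(m), tolerance = 1e-9)
  expect_equal(m@ciHigh, gridValues(m), tolerance = 1e-9)
  # fixed seed reproduces percentiles exactly
  fitN <- fitAllometry(generatePlots(allometrySimConfig(seed = 4L)))
  m1 <- monteCarloACD(fitN, cells, nDraws = 200L, seed = 9L)
  m2 <- monteCarloACD(fitN, cells, nDraws = 200L, seed = 9L)
  expect_identical(m1@ciLow, m2@ciLow)
  expect_identical(m1@landscapeCI, m2@landscapeCI)
  # central estimate sits inside the bounds
  expect_true(all(m1@ciLow <= gridValues(m1) + 1e-9))
  expect_true(all(m1@ciHigh >= gridValues(m1) - 1e-9))
  expect_error(monteCarloACD(fitN, cells, nDraws = 1L), "nDraws")
})

test_that("landscape-mean CI width shrinks as 1/sqrt(n cells)", {
  fit <- fitAllometry(generatePlots(allometrySimConfig(seed = 6L)))
  mkCells <- function(n) gridLayer(matrix(20, n, n), resolution = 70)
  w <- vapply(c(4L, 8L), function(n) {
    m <- monteCarloACD(fit, mkCells(n), nDraws = 4000L, seed = 2L)
    diff(m@landscapeCI)
  }, numeric(1))
  # 4x the cells halves the width (residual-only CI on iid noise)
  expect_lt(abs(w[1] / w[2] - 2), 0.3)
})

test_that("acdChange mirrors headline arithmetic and recovers a known loss", {
  fit <- fitAllometry(generatePlots(allometrySimConfig(seed = 8L)))
  # pure arithmetic: landscape means 100 -> 82.4 is a -17.6% change
  pre <- monteCarloACD(fit, gridLayer(matrix(20, 2, 2), resolution = 70),
                       nDraws = 10L, seed = 1L, residualSeed = 2L)
  post <- pre
  vals <- gridValues(pre) * 0.824
  post@values <- vals
  post@landscapeDraws <- pre@landscapeDraws * 0.824
  post@settings$residualSeed <- 3L
  ch <- acdChange(pre, post)
  expect_equal(ch$landscape$pctChange, -17.6, tolerance = 1e-9)
  # identical maps: zero change (shared residual seed warns, by design)
  same <- suppressWarnings(acdChange(pre, pre))
  expect_equal(same$landscape$change, 0)
  expect_true(all(gridValues(same$cellChange) == 0))
  # a synthetic blowdown of known severity is recovered within the MC CI
  chm <- generateCHM(syntheticForestConfig(extentM = 140, seed = 13L))
  blow <- applyBlowdown(chm, 0.25, seed = 14L)
  cellPre <- aggregateMean(chm, 56L)     # 1.25 m -> 70 m cells
  cellPost <- aggregateMean(blow$chm, 56L)
  truthChange <- mean(0.47 * 3.8 * gridValues(cellPost)^1.27) -
    mean(0.47 * 3.8 * gridValues(cellPre)^1.27)
  plots <- generatePlots(allometrySimConfig(seed = 15L))
  fitB <- fitAllometry(plots)
  mapPre <- monteCarloACD(fitB, cellPre, nDraws = 500L, seed = 16L,
                          residualSeed = 17L, perturbParams = TRUE)
  mapPost <- monteCarloACD(fitB, cellPost, nDraws = 500L, seed = 16L,
                           residualSeed = 18L, perturbParams = TRUE)
  chB <- acdChange(mapPre, mapPost)
  expect_lt(chB$landscape$change, 0)
  expect_gte(truthChange, chB$landscape$changeCI[1])
  expect_lte(truthChange, chB$landscape$changeCI[2])
})

test_that("acdChange rejects mismatched inputs", {
  fit <- fitAllometry(generatePlots(allometrySimConfig(seed = 8L)))
  cells <- gridLayer(matrix(20, 2, 2), resolution = 70)
  a <- monteCarloACD(fit, cells, nDraws = 10L, seed = 1L)
  fit2 <- fitAllometry(generatePlots(allometrySimConfig(seed = 9L)))
  b <- monteCarloACD(fit2, cells, nDraws = 10L, seed = 1L)
  expect_error(acdChange(a, b), "same allometric fit")
  c2 <- monteCarloACD(fit, gridLayer(matrix(20, 3, 3), resolution = 70),
                      nDraws = 10L, seed = 1L)
  expect_error(acdChange(a, c2), "identical grid")
  expect_warning(acdChange(a, a2 <- monteCarloACD(fit, cells, nDraws = 10L,
                                                  seed = 1L)),
                 "residual seeds")
})
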