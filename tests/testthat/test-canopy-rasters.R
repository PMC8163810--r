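makePoints <- function(x, y, z, rn = 1L, angle = 0) {
  data.frame(x = x, y = y, z = z, return_number = rn, scan_angle = angle)
}

test_that("filterReturns applies the first-return and scan-angle rules", {
  pts <- makePoints(1:3, 1:3, 1:3, rn = c(1L, 2L, 1L), angle = c(0, 0, 20))
  expect_identical(nrow(filterReturns(pts, 15)), 1L)
  # wide threshold over first returns is the identity
  pts2 <- makePoints(1:5, 1:5, 1:5, rn = 1L, angle = seq(-40, 40, 20))
  expect_identical(filterReturns(pts2, 90), pts2)
  # brute-force predicate count on a mixed synthetic set
  set.seed(17)
  pts3 <- makePoints(runif(1000), runif(1000), runif(1000),
                     rn = sample(1:3, 1000, TRUE),
                     angle = runif(1000, -30, 30))
  expect_identical(nrow(filterReturns(pts3, 15)),
                   sum(pts3$return_number == 1 & abs(pts3$scan_angle) <= 15))
  # order is preserved
  expect_false(is.unsorted(filterReturns(pts3, 15)$x[order(
    filterReturns(pts3, 15)$x)]))
})

test_that("subsampleDensity hits the target count deterministically", {
  set.seed(3)
  pts <- makePoints(runif(1000, 0, 10), runif(1000, 0, 1), rnorm(1000))
  sub <- subsampleDensity(pts, 10, 10, seed = 4L)
  expect_identical(nrow(sub), 100L)
  expect_identical(sub, subsampleDensity(pts, 10, 10, seed = 4L))
  # at-or-below target returns the input with a warning
  expect_warning(out <- subsampleDensity(pts, 200, 10, seed = 1L), "density")
  expect_identical(out, pts)
})

test_that("heightAboveGround subtracts the interpolated terrain", {
  flat <- heightRaster(matrix(100, 10, 10), resolution = 10)
  p <- makePoints(50, 50, 125)
  expect_equal(heightAboveGround(p, flat)$z, 25)
  # below-ground points clamp to zero
  expect_equal(heightAboveGround(makePoints(50, 50, 99), flat)$z, 0)
  # tilted plane: elevation = 2 + 0.1 x + 0.05 y, sampled at cell centres,
  # is reproduced exactly by bilinear interpolation (plane through centres)
  nr <- 20; nc <- 20; res <- 5
  cx <- (seq_len(nc) - 0.5) * res
  cy <- rev((seq_len(nr) - 0.5) * res)
  plane <- outer(cy, cx, function(y, x) 2 + 0.1 * x + 0.05 * y)
  dtm <- heightRaster(plane, resolution = res)
  set.seed(5)
  px <- runif(50, 2.5, 97.5); py <- runif(50, 2.5, 97.5)
  pts <- makePoints(px, py, 40)
  expect_equal(heightAboveGround(pts, dtm)$z,
               pmax(40 - (2 + 0.1 * px + 0.05 * py), 0), tolerance = 1e-9)
  # points outside the DTM are an error naming the count
  expect_error(heightAboveGround(makePoints(-5, 50, 10), flat), "1 point")
})

test_that("applyVerticalBias shifts heights uniformly and invertibly", {
  p <- makePoints(1, 1, 20.7)
  expect_equal(applyVerticalBias(p, 0.7)$z, 20)
  expect_identical(applyVerticalBias(p, 0), p)
  expect_equal(applyVerticalBias(applyVerticalBias(p, 0.7), -0.7), p)
})

test_that("rasterizeTIN interpolates the Delaunay surface exactly", {
  # flat TIN: all in-hull pixels equal the common height
  pts <- makePoints(c(0, 20, 20, 0), c(0, 0, 20, 20), 7)
  r <- rasterizeTIN(pts, resolutionM = 1.25, extent = c(0, 20, 0, 20))
  v <- gridValues(r)
  expect_true(all(abs(v[!is.na(v)] - 7) < 1e-12))
  # analytic plane z = 0.1 x + 0.2 y reproduced at every in-hull centre
  set.seed(9)
  x <- c(runif(300, 0, 30), 0, 30, 0, 30); y <- c(runif(300, 0, 30), 0, 0, 30, 30)
  pp <- makePoints(x, y, 0.1 * x + 0.2 * y)
  rp <- rasterizeTIN(pp, resolutionM = 1.25, extent = c(0, 30, 0, 30))
  cx <- (seq_len(24) - 0.5) * 1.25
  cy <- rev(cx)
  truth <- outer(cy, cx, function(yy, xx) 0.1 * xx + 0.2 * yy)
  vv <- gridValues(rp)
  expect_lt(max(abs(vv - truth), na.rm = TRUE), 1e-9)
  expect_false(anyNA(vv))
  # pixel centres coincident with points reproduce point heights exactly
  g <- expand.grid(x = c(0.625, 1.875, 3.125), y = c(0.625, 1.875, 3.125))
  pg <- makePoints(g$x, g$y, seq_len(9))
  rg <- rasterizeTIN(pg, resolutionM = 1.25, extent = c(0, 3.75, 0, 3.75))
  expect_equal(gridValues(rg)[cbind(3 - (g$y - 0.625) / 1.25,
                                    (g$x - 0.625) / 1.25 + 1)],
               as.numeric(seq_len(9)), tolerance = 1e-12)
  # degenerate inputs error
  expect_error(rasterizeTIN(makePoints(1:2, 1:2, 1:2)), "3 points")
  expect_error(rasterizeTIN(makePoints(1:5, 1:5, 1:5)), "collinear")
})

test_that("tiled TIN rasterization matches the single-tile result", {
  set.seed(23)
  n <- 4000
  x <- runif(n, 0, 60); y <- runif(n, 0, 60)
  pts <- makePoints(x, y, 10 + 0.05 * x + 0.02 * y + rnorm(n, 0, 0.5))
  whole <- rasterizeTIN(pts, extent = c(0, 60, 0, 60))
  tiled <- rasterizeTIN(pts, extent = c(0, 60, 0, 60),
                        maxPointsPerTile = 900L, tileBufferM = 10)
  vw <- gridValues(whole); vt <- gridValues(tiled)
  ok <- !is.na(vw) & !is.na(vt)
  # interior pixels agree; allow the odd sliver where buffered triangulations
  # differ near tile borders
  expect_gt(mean(abs(vw[ok] - vt[ok]) < 1e-9), 0.999)
})

test_that("rasterizeMean averages points per half-open pixel", {
  pts <- makePoints(c(2, 3, 7), c(2, 3, 8), c(10, 20, 5))
  r <- rasterizeMean(pts, resolutionM = 5, extent = c(0, 10, 0, 10))
  v <- gridValues(r)
  expect_equal(v[2, 1], 15)       # two points in the lower-left pixel
  expect_equal(v[1, 2], 5)        # single point upper-right
  expect_true(is.na(v[1, 1]) && is.na(v[2, 2]))  # empty pixels are nodata
  # brute-force group-by mean on a synthetic scatter
  set.seed(31)
  n <- 500
  sp <- makePoints(runif(n, 0, 25), runif(n, 0, 25), rnorm(n, 15, 4))
  rr <- rasterizeMean(sp, resolutionM = 5, extent = c(0, 25, 0, 25))
  col <- floor(sp$x / 5) + 1; row <- 5 - floor(sp$y / 5)
  for (cell in split(seq_len(n), paste(row, col))) {
    rc <- c(row[cell[1]], col[cell[1]])
    expect_equal(gridValues(rr)[rc[1], rc[2]], mean(pmax(sp$z[cell], 0)),
                 tolerance = 1e-12)
  }
})

test_that("heightChange differences aligned rasters and propagates nodata", {
  a <- heightRaster(matrix(20, 3, 3), resolution = 5)
  bVals <- matrix(15, 3, 3); bVals[2, 2] <- NA
  b <- heightRaster(bVals, resolution = 5)
  ch <- heightChange(a, b)
  expect_equal(gridValues(ch)[1, 1], -5)
  expect_true(is.na(gridValues(ch)[2, 2]))
  expect_true(all(gridValues(heightChange(a, a)) == 0))
  # geometry mismatch errors
  expect_error(heightChange(a, heightRaster(matrix(1, 3, 3), resolution = 4)),
               "identical grid")
})

test_that("meanTCH averages pixel centres inside the footprint", {
  expect_equal(meanTCH(uniformCHM(22.2), c(0, 10, 0, 10)), 22.2)
  two <- heightRaster(matrix(c(10, 30), 1, 2), resolution = 5)
  expect_equal(meanTCH(two, c(0, 10, 0, 5)), 20)
  # brute-force masked mean on a random footprint
  set.seed(41)
  r <- heightRaster(matrix(runif(400, 5, 30), 20, 20), resolution = 5)
  fp <- c(13, 64, 22, 78)
  cx <- (seq_len(20) - 0.5) * 5
  cy <- rev(cx)
  inside <- outer(cy >= fp[3] & cy < fp[4], cx >= fp[1] & cx < fp[2], "&")
  expect_equal(meanTCH(r, fp), mean(gridValues(r)[inside]))
  expect_error(meanTCH(r, c(1000, 1010, 0, 5)), "no pixel centres")
})

test_that("filter-subsample-rasterize pipeline is order-stable under a seed", {
  set.seed(51)
  n <- 3000
  pts <- makePoints(runif(n, 0, 40), runif(n, 0, 40), runif(n, 0, 30),
                    rn = sample(1:2, n, TRUE), angle = runif(n, -25, 25))
  run <- function() {
    f <- filterReturns(pts, 15)
    s <- subsampleDensity(f, 0.5, 1600, seed = 7L)
    rasterizeMean(s, resolutionM = 5, extent = c(0, 40, 0, 40))
  }
  expect_identical(gridValues(run()), gridValues(run()))
})

test_that("aggregateMean and resampleAreaWeighted reduce grids consistently", {
  v <- matrix(as.numeric(1:16), 4, 4)
  r <- gridLayer(v, resolution = 5)
  agg <- aggregateMean(r, 2L)
  expect_equal(gridValues(agg)[1, 1], mean(v[1:2, 1:2]))
  expect_equal(gridResolution(agg), 10)
  # resampling to the same factor-of-2 grid equals block means
  rs <- resampleAreaWeighted(r, 10)
  expect_equal(gridValues(rs), gridValues(agg), tolerance = 1e-12)
  # a uniform raster resamples to the uniform value on any grid
  u <- gridLayer(matrix(3.5, 6, 6), resolution = 5)
  expect_true(all(abs(gridValues(resampleAreaWeighted(u, 7)) - 3.5) < 1e-12))
})

test_that("rasterizeMean of uniformly populated pixels preserves the mean height", {
  # every pixel gets the same number of points: raster mean == point mean
  g <- expand.grid(px = 0:4, py = 0:4, i = 1:3)
  set.seed(61)
  x <- g$px * 5 + runif(nrow(g), 0, 5)
  y <- g$py * 5 + runif(nrow(g), 0, 5)
  z <- runif(nrow(g), 10, 30)
  r <- rasterizeMean(makePoints(x, y, z), resolutionM = 5,
                     extent = c(0, 25, 0, 25))
  expect_equal(mean(gridValues(r)), mean(z), tolerance = 1e-12)
})
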