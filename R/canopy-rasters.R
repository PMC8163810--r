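#' @include raster-io.R
NULL

#' Filter lidar returns by return number and scan angle
#'
#' Retains first returns (`return_number == 1`) with absolute scan angle at
#' or below the threshold, preserving input order. First returns represent
#' the highest intercepted surface; restricting the scan angle limits
#' geometric distortion from off-nadir sampling.
#'
#' @param points data.frame with columns `x,y,z,return_number,scan_angle`.
#' @param maxAbsScanAngleDeg scan-angle cutoff in degrees (default 15).
#' @return the filtered data.frame; an empty result is allowed (a message is
#'   emitted).
#' @export
filterReturns <- function(points, maxAbsScanAngleDeg = 15) {
  checkPoints(points)
  keep <- points$return_number == 1 &
    abs(points$scan_angle) <= maxAbsScanAngleDeg
  out <- points[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    message("filterReturns: no points survive the filter")
  out
}

#' Randomly subsample points to a target density
#'
#' Uniform sampling without replacement down to
#' `round(targetDensityPtsM2 * areaM2)` points, used to homogenize surveys
#' of different native density. If the input is already at or below the
#' target density it is returned unchanged with a warning.
#'
#' @param points data.frame of points.
#' @param targetDensityPtsM2 target density (points per square metre).
#' @param areaM2 survey area (square metres).
#' @param seed RNG seed.
#' @return data.frame of subsampled points, in original order.
#' @export
subsampleDensity <- function(points, targetDensityPtsM2, areaM2, seed = 1L) {
  checkPoints(points)
  nTarget <- round(targetDensityPtsM2 * areaM2)
  if (nrow(points) <= nTarget) {
    warning("point density is already at or below the target; returning input",
            call. = FALSE)
    return(points)
  }
  idx <- withSeed(seed, sample.int(nrow(points), nTarget))
  points[sort(idx), , drop = FALSE]
}

## internal: bilinear interpolation of a raster at arbitrary coordinates.
## Interpolates between pixel centres; coordinates in the outer half-pixel
## margin are clamped to the centre grid (nearest-edge continuation).
bilinearSample <- function(raster, x, y) {
  v <- gridValues(raster)
  nr <- nrow(v); nc <- ncol(v)
  res <- gridResolution(raster)
  org <- gridOrigin(raster)
  gx <- (x - org[1]) / res - 0.5          # 0-based fractional column
  gy <- (org[2] + nr * res - y) / res - 0.5  # 0-based fractional row (top first)
  gx <- pmin(pmax(gx, 0), nc - 1)
  gy <- pmin(pmax(gy, 0), nr - 1)
  c0 <- pmin(floor(gx), nc - 2); fx <- gx - c0
  r0 <- pmin(floor(gy), nr - 2); fy <- gy - r0
  if (nc == 1L) { c0 <- rep(0, length(gx)); fx <- rep(0, length(gx)) }
  if (nr == 1L) { r0 <- rep(0, length(gy)); fy <- rep(0, length(gy)) }
  i00 <- cbind(r0 + 1, c0 + 1)
  i01 <- cbind(r0 + 1, pmin(c0 + 2, nc))
  i10 <- cbind(pmin(r0 + 2, nr), c0 + 1)
  i11 <- cbind(pmin(r0 + 2, nr), pmin(c0 + 2, nc))
  v[i00] * (1 - fx) * (1 - fy) + v[i01] * fx * (1 - fy) +
    v[i10] * (1 - fx) * fy + v[i11] * fx * fy
}

#' Convert point elevations to heights above ground
#'
#' Subtracts the ground elevation, bilinearly interpolated from a digital
#' terrain model, from each point's `z`. Negative results (points below the
#' interpolated ground) are clamped to zero, since negative canopy height is
#' physically meaningless.
#'
#' @param points data.frame of points with `z` as elevation (m).
#' @param dtm a [GridLayer-class]/[HeightRaster-class] of ground elevation.
#' @return the points with `z` replaced by height above ground.
#' @export
heightAboveGround <- function(points, dtm) {
  checkPoints(points)
  ext <- gridExtent(dtm)
  outside <- points$x < ext[1] | points$x >= ext[2] |
    points$y < ext[3] | points$y >= ext[4]
  if (any(outside))
    stop(sum(outside), " point(s) fall outside the DTM extent", call. = FALSE)
  ground <- bilinearSample(dtm, points$x, points$y)
  if (any(is.na(ground)))
    stop("DTM has nodata under ", sum(is.na(ground)), " point(s)",
         call. = FALSE)
  points$z <- pmax(points$z - ground, 0)
  points
}

#' Apply a uniform vertical bias correction
#'
#' Shifts all point heights down by `biasM`, correcting a known constant
#' positive bias of one survey epoch relative to another (e.g. estimated
#' from surfaces visible in both surveys).
#'
#' @param points data.frame of points.
#' @param biasM bias to remove (m); the correction subtracts it from `z`.
#' @return the corrected points.
#' @export
applyVerticalBias <- function(points, biasM) {
  checkPoints(points)
  points$z <- points$z - biasM
  points
}

## internal: TIN interpolation of one tile through interp::interp
tinTile <- function(x, y, z, xo, yo) {
  g <- interp::interp(x = x, y = y, z = z, xo = xo, yo = yo,
                      method = "linear", duplicate = "mean")
  # g$z[i, j] is (xo[i], yo[j]); convert to map orientation (north first)
  t(g$z)[rev(seq_along(yo)), , drop = FALSE]
}

#' Rasterize points to a canopy height model via a Delaunay TIN
#'
#' Builds the Delaunay triangulation of the points and evaluates the
#' piecewise-linear surface at every pixel centre, so every pixel inside the
#' convex hull has a height value even where no return fell in it. Pixels
#' outside the hull are nodata. Interpolated values are clamped at 0 (canopy
#' heights are non-negative).
#'
#' For large point sets the extent is processed in buffered square tiles:
#' each tile is triangulated from the points within its buffer, which leaves
#' interior pixels identical to the global triangulation at realistic point
#' densities and keeps memory bounded.
#'
#' @param points data.frame of height-normalized points (>= 3, not all
#'   collinear).
#' @param resolutionM pixel size (m); 1.25 m is the conventional grid for
#'   gap delineation.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the point bounding
#'   box snapped outward to whole pixels.
#' @param maxPointsPerTile tiling threshold (points).
#' @param tileBufferM tile buffer width (m).
#' @param crs optional CRS label for the output.
#' @return a [HeightRaster-class].
#' @export
rasterizeTIN <- function(points, resolutionM = 1.25, extent = NULL,
                         maxPointsPerTile = 25000L, tileBufferM = 10,
                         crs = NA_character_) {
  checkPoints(points)
  if (nrow(points) < 3L)
    stop("need at least 3 points to triangulate", call. = FALSE)
  spread <- cbind(points$x - mean(points$x), points$y - mean(points$y))
  if (qr(spread)$rank < 2L)
    stop("points are collinear; cannot triangulate", call. = FALSE)
  if (is.null(extent)) {
    extent <- c(floor(min(points$x) / resolutionM) * resolutionM,
                ceiling(max(points$x) / resolutionM) * resolutionM,
                floor(min(points$y) / resolutionM) * resolutionM,
                ceiling(max(points$y) / resolutionM) * resolutionM)
  }
  nc <- round((extent[2] - extent[1]) / resolutionM)
  nr <- round((extent[4] - extent[3]) / resolutionM)
  xo <- extent[1] + (seq_len(nc) - 0.5) * resolutionM
  yo <- extent[3] + (seq_len(nr) - 0.5) * resolutionM   # ascending
  vals <- matrix(NA_real_, nr, nc)
  nTilesSide <- ceiling(sqrt(nrow(points) / maxPointsPerTile))
  if (nTilesSide <= 1L) {
    vals <- tinTile(points$x, points$y, points$z, xo, yo)
  } else {
    xBreaks <- seq(extent[1], extent[2], length.out = nTilesSide + 1L)
    yBreaks <- seq(extent[3], extent[4], length.out = nTilesSide + 1L)
    for (ti in seq_len(nTilesSide)) for (tj in seq_len(nTilesSide)) {
      xcols <- which(xo >= xBreaks[ti] & xo <= xBreaks[ti + 1L])
      yrows <- which(yo >= yBreaks[tj] & yo <= yBreaks[tj + 1L])
      if (!length(xcols) || !length(yrows)) next
      sel <- points$x >= xBreaks[ti] - tileBufferM &
        points$x <= xBreaks[ti + 1L] + tileBufferM &
        points$y >= yBreaks[tj] - tileBufferM &
        points$y <= yBreaks[tj + 1L] + tileBufferM
      if (sum(sel) < 3L) next
      tile <- tinTile(points$x[sel], points$y[sel], points$z[sel],
                      xo[xcols], yo[yrows])
      vals[nr - rev(yrows) + 1L, xcols] <- tile
    }
  }
  heightRaster(pmax(vals, 0), resolution = resolutionM,
               origin = c(extent[1], extent[3]), crs = crs)
}

#' Rasterize points to per-pixel mean height
#'
#' Pixel value is the arithmetic mean of the heights of all points whose
#' coordinates fall in the half-open pixel footprint; pixels containing no
#' points are nodata. This is the conventional top-of-canopy-height (TCH)
#' grid when applied to first returns at 5 m resolution.
#'
#' @param points data.frame of height-normalized first-return points.
#' @param resolutionM pixel size (m), default 5.
#' @param extent `c(xmin, xmax, ymin, ymax)`; defaults to the point bounding
#'   box snapped outward to whole pixels.
#' @param crs optional CRS label.
#' @return a [HeightRaster-class].
#' @export
rasterizeMean <- function(points, resolutionM = 5, extent = NULL,
                          crs = NA_character_) {
  checkPoints(points)
  if (is.null(extent)) {
    extent <- c(floor(min(points$x) / resolutionM) * resolutionM,
                ceiling(max(points$x) / resolutionM) * resolutionM,
                floor(min(points$y) / resolutionM) * resolutionM,
                ceiling(max(points$y) / resolutionM) * resolutionM)
  }
  nc <- round((extent[2] - extent[1]) / resolutionM)
  nr <- round((extent[4] - extent[3]) / resolutionM)
  geom <- gridLayer(matrix(NA_real_, nr, nc), resolution = resolutionM,
                    origin = c(extent[1], extent[3]))
  px <- pointToPixel(points$x, points$y, geom)
  keep <- px$inside
  idx <- (px$col[keep] - 1L) * nr + px$row[keep]
  sums <- rowsum(pmax(points$z[keep], 0), idx)
  counts <- rowsum(rep(1, length(idx)), idx)
  vals <- matrix(NA_real_, nr, nc)
  vals[as.integer(rownames(sums))] <- sums / counts
  heightRaster(vals, resolution = resolutionM,
               origin = c(extent[1], extent[3]), crs = crs)
}

#' Per-pixel canopy height change between two epochs
#'
#' Final minus initial height on an identical grid; nodata wherever either
#' epoch is nodata.
#'
#' @param pre,post [HeightRaster-class] objects on the same grid.
#' @return a [HeightChangeRaster-class].
#' @export
heightChange <- function(pre, post) {
  stopIfGeometryMismatch(pre, post, "height rasters")
  new("HeightChangeRaster", values = gridValues(post) - gridValues(pre),
      resolution = gridResolution(pre), origin = gridOrigin(pre),
      crs = gridCRS(pre))
}

#' Mean canopy height within a footprint
#'
#' Mean over non-nodata pixels whose centres fall inside the rectangular
#' footprint (half-open on the max edges, like pixel footprints). This is
#' how plot-level TCH is extracted from the 5 m grid.
#'
#' @param raster a [HeightRaster-class] (or any [GridLayer-class]).
#' @param footprint `c(xmin, xmax, ymin, ymax)` in metres.
#' @return scalar mean height (m).
#' @export
meanTCH <- function(raster, footprint) {
  cx <- pixelCentersX(raster)
  cy <- pixelCentersY(raster)
  cols <- which(cx >= footprint[1] & cx < footprint[2])
  rows <- which(cy >= footprint[3] & cy < footprint[4])
  if (!length(cols) || !length(rows))
    stop("footprint contains no pixel centres", call. = FALSE)
  v <- gridValues(raster)[rows, cols]
  if (all(is.na(v)))
    stop("footprint covers only nodata pixels", call. = FALSE)
  mean(v, na.rm = TRUE)
}

#' Aggregate a raster by an integer factor of pixels
#'
#' Block mean over `factor x factor` pixel blocks (NA-aware); used to build
#' the 0.5-ha analysis grid from the 5 m TCH grid (factor 14 gives 70 m
#' cells, the closest grid-aligned approximation to half-hectare cells).
#' Trailing rows/columns that do not fill a block are dropped.
#'
#' @param raster a [GridLayer-class] (or subclass).
#' @param factor integer aggregation factor (>= 1).
#' @return a [GridLayer-class] at `factor` times the input resolution.
#' @export
aggregateMean <- function(raster, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  v <- gridValues(raster)
  nr <- (nrow(v) %/% factor) * factor
  nc <- (ncol(v) %/% factor) * factor
  if (nr < factor || nc < factor)
    stop("raster smaller than one aggregation block", call. = FALSE)
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  rowGrp <- rep(seq_len(nr %/% factor), each = factor)
  colGrp <- rep(seq_len(nc %/% factor), each = factor)
  # block means ignoring NA
  sums <- rowsum(t(rowsum(ifelse(is.na(v), 0, v), rowGrp)), colGrp)
  cnts <- rowsum(t(rowsum(1 - is.na(v) + 0, rowGrp)), colGrp)
  out <- t(sums / ifelse(cnts == 0, NA, cnts))
  dimnames(out) <- NULL
  # top rows of the input must stay the top rows of the output; dropping
  # trailing rows keeps the origin's x but lifts ymin
  newRes <- gridResolution(raster) * factor
  ymax <- gridOrigin(raster)[2] +
    nrow(gridValues(raster)) * gridResolution(raster)
  gridLayer(out, resolution = newRes,
            origin = c(gridOrigin(raster)[1], ymax - nrow(out) * newRes),
            crs = gridCRS(raster))
}

#' Area-weighted resampling onto a coarser grid
#'
#' Each target cell value is the overlap-area-weighted mean of the source
#' pixels intersecting it (NA source pixels are excluded from the weights).
#' Used to pair fine-scale carbon maps with coarser optical pixels.
#'
#' @param layer source [GridLayer-class].
#' @param resolutionM target pixel size (m).
#' @param extent target extent `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   source extent.
#' @return a [GridLayer-class] on the target grid.
#' @export
resampleAreaWeighted <- function(layer, resolutionM, extent = NULL) {
  if (is.null(extent)) extent <- gridExtent(layer)
  v <- gridValues(layer)
  srcRes <- gridResolution(layer)
  org <- gridOrigin(layer)
  nc <- round((extent[2] - extent[1]) / resolutionM)
  nr <- round((extent[4] - extent[3]) / resolutionM)
  # separable overlap weights: columns (x) and rows (y)
  overlap1 <- function(srcLo, srcHi, tgtLo, tgtHi) {
    W <- matrix(0, length(srcLo), length(tgtLo))
    for (j in seq_along(tgtLo))
      W[, j] <- pmax(pmin(srcHi, tgtHi[j]) - pmax(srcLo, tgtLo[j]), 0)
    W
  }
  srcXlo <- org[1] + (seq_len(ncol(v)) - 1) * srcRes
  srcYhi <- org[2] + nrow(v) * srcRes - (seq_len(nrow(v)) - 1) * srcRes
  tgtXlo <- extent[1] + (seq_len(nc) - 1) * resolutionM
  tgtYhi <- extent[4] - (seq_len(nr) - 1) * resolutionM
  Wx <- overlap1(srcXlo, srcXlo + srcRes, tgtXlo, tgtXlo + resolutionM)
  Wy <- overlap1(srcYhi - srcRes, srcYhi, tgtYhi - resolutionM, tgtYhi)
  vz <- ifelse(is.na(v), 0, v)
  msk <- 1 - is.na(v)
  num <- t(Wy) %*% vz %*% Wx
  den <- t(Wy) %*% msk %*% Wx
  out <- num / ifelse(den <= 0, NA, den)
  gridLayer(out, resolution = resolutionM,
            origin = c(extent[1], extent[3]), crs = gridCRS(layer))
}
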