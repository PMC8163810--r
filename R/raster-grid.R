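#' @include AllClasses.R
NULL

## internal: run expr with a private RNG stream, restoring global state.
## Every seeded function in the package funnels through this, so no call
## disturbs (or depends on) the caller's RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## internal: geometry equality check used by every two-raster operation
sameGeometry <- function(a, b, tol = 1e-9) {
  isTRUE(abs(a@resolution - b@resolution) <= tol) &&
    all(abs(a@origin - b@origin) <= tol) &&
    identical(dim(gridValues(a))[1:2], dim(gridValues(b))[1:2])
}

stopIfGeometryMismatch <- function(a, b, what = "rasters") {
  if (!sameGeometry(a, b))
    stop(what, " must share an identical grid (resolution, origin, dimensions)",
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a single-band raster layer
#'
#' @param values numeric matrix in map orientation (row 1 = northernmost).
#' @param resolution pixel edge length (m).
#' @param origin `c(xmin, ymin)` of the grid's lower-left corner (m).
#' @param crs optional CRS label carried as metadata.
#' @return a [GridLayer-class].
#' @examples
#' r <- gridLayer(matrix(1:6, 2), resolution = 5)
#' gridExtent(r)
#' @export
gridLayer <- function(values, resolution = 1, origin = c(0, 0),
                      crs = NA_character_) {
  new("GridLayer", values = values, resolution = resolution,
      origin = origin, crs = crs)
}

#' Construct a canopy height raster
#'
#' @inheritParams gridLayer
#' @return a [HeightRaster-class]; heights must be >= 0 or `NA`.
#' @export
heightRaster <- function(values, resolution = 1.25, origin = c(0, 0),
                         crs = NA_character_) {
  new("HeightRaster", values = values, resolution = resolution,
      origin = origin, crs = crs)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname gridValues
#' @export
setMethod("gridValues", "GridLayer", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridValues", "GapLabelMap", function(x) x@labels)

#' @rdname gridValues
#' @export
setMethod("gridValues", "AcdMap", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridValues", "BandRaster", function(x) x@values)

#' @rdname gridValues
#' @export
setMethod("gridValues", "FractionMap", function(x) x@fractions)

#' @rdname gridResolution
#' @export
setMethod("gridResolution", "RasterGeometry", function(x) x@resolution)

#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "RasterGeometry", function(x) x@origin)

#' @rdname gridCRS
#' @export
setMethod("gridCRS", "RasterGeometry", function(x) x@crs)

#' @rdname gridExtent
#' @export
setMethod("gridExtent", "RasterGeometry", function(x) {
  d <- dim(gridValues(x))
  c(x@origin[1], x@origin[1] + d[2] * x@resolution,
    x@origin[2], x@origin[2] + d[1] * x@resolution)
})

## internal: pixel-centre coordinate vectors.
## columns west->east; rows are returned top (north) first to match the
## matrix orientation.
pixelCentersX <- function(x) {
  d <- dim(gridValues(x))
  x@origin[1] + (seq_len(d[2]) - 0.5) * x@resolution
}
pixelCentersY <- function(x) {
  d <- dim(gridValues(x))
  ymax <- x@origin[2] + d[1] * x@resolution
  ymax - (seq_len(d[1]) - 0.5) * x@resolution
}

## internal: half-open pixel indices for point coordinates.
## Returns NA row/col for points outside [xmin, xmax) x [ymin, ymax).
pointToPixel <- function(x, y, geom) {
  d <- dim(gridValues(geom))
  res <- geom@resolution
  col <- floor((x - geom@origin[1]) / res) + 1
  rowFromBottom <- floor((y - geom@origin[2]) / res) + 1
  ok <- col >= 1 & col <= d[2] & rowFromBottom >= 1 & rowFromBottom <= d[1]
  col[!ok] <- NA_integer_
  row <- d[1] - rowFromBottom + 1
  row[!ok] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), inside = ok)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

.showGrid <- function(object, what) {
  v <- gridValues(object)
  d <- dim(v)[1:2]
  ext <- gridExtent(object)
  cat(sprintf("%s: %d x %d pixels @ %g m\n", what, d[1], d[2],
              object@resolution))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]%s\n", ext[1], ext[2], ext[3],
              ext[4],
              if (is.na(object@crs)) "" else paste0("  crs: ", object@crs)))
  vv <- v[!is.na(v)]
  if (length(vv))
    cat(sprintf("  values: min %.3g  mean %.3g  max %.3g  (nodata: %d px)\n",
                min(vv), mean(vv), max(vv), sum(is.na(v))))
  invisible(object)
}

setMethod("show", "GridLayer", function(object)
  .showGrid(object, class(object)))

setMethod("show", "GapLabelMap", function(object) {
  n <- max(object@labels, 0, na.rm = TRUE)
  cat(sprintf("GapLabelMap: %d gaps at height <= %g m (8-connectivity)\n",
              n, object@threshold))
  .showGrid(object, "  labels")
})

setMethod("show", "AcdMap", function(object) {
  cat(sprintf("AcdMap: carbon fraction %.2f, %d Monte Carlo draws\n",
              object@carbonFraction, object@settings$nDraws))
  cat(sprintf("  landscape mean ACD: %.2f Mg C ha^-1 (95%% CI %.2f-%.2f)\n",
              mean(object@values[!is.na(object@values)]),
              object@landscapeCI[1], object@landscapeCI[2]))
  .showGrid(object, "  cells")
})

setMethod("show", "ZetaPosterior", function(object) {
  s <- object@settings
  cat(sprintf("ZetaPosterior: lambda median %.3f (95%% CrI %.3f-%.3f)\n",
              object@lambdaMedian, object@cri[1], object@cri[2]))
  cat(sprintf("  %d retained samples (chain %d, burn-in %d, thin %d), %d gap sizes\n",
              length(object@chain), s$nTotal, s$nBurnin, s$thin, object@nSizes))
  cat(sprintf("  acceptance rate %.2f, prior U(%g, %g)\n",
              object@acceptanceRate, s$priorMin, s$priorMax))
})

setMethod("show", "AllometricFit", function(object) {
  cat(sprintf("AllometricFit: AGBD = %.4g * TCH^%.4g  (n = %d plots)\n",
              object@a, object@b, object@n))
  cat(sprintf("  sigma = %.3g Mg ha^-1, r2 = %.3f, RMSE = %.2f%% of mean AGBD\n",
              object@sigma, object@r2, object@rmsePct))
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d height classes of %g m (%d pixels)\n",
              object@nClasses, object@classWidth, sum(object@counts)))
})

setMethod("show", "SteadyState", function(object) {
  cat(sprintf("SteadyState: mean equilibrium height %.2f m", object@meanHeight))
  if (length(object@meanHeightCI) == 2L)
    cat(sprintf(" (95%% CI %.2f-%.2f, %d draws)", object@meanHeightCI[1],
                object@meanHeightCI[2], object@nDraws))
  cat(sprintf("\n  %d classes of %g m\n", length(object@distribution),
              diff(object@edges[1:2])))
})

setMethod("show", "FractionMap", function(object) {
  cat(sprintf("FractionMap: endmembers %s\n",
              paste(object@endmemberNames, collapse = ", ")))
  for (i in seq_along(object@endmemberNames))
    cat(sprintf("  %s: mean %.3f\n", object@endmemberNames[i],
                mean(object@fractions[, , i], na.rm = TRUE)))
})

setMethod("show", "RecoveryScenario", function(object) {
  cat(sprintf("RecoveryScenario: ACD loss %.2f Mg C ha^-1\n", object@acdLoss))
  cat(sprintf("  long-term gain %.2f Mg C ha^-1 yr^-1; elevated phase %d yr\n",
              object@longTermGain, length(object@elevatedGains)))
})

## ---------------------------------------------------------------------------
## Small accessors for posterior/matrix classes
## ---------------------------------------------------------------------------

#' @rdname posteriorChain
#' @export
setMethod("posteriorChain", "ZetaPosterior", function(x) x@chain)

#' @rdname lambdaMedian
#' @export
setMethod("lambdaMedian", "ZetaPosterior", function(x) x@lambdaMedian)

#' @rdname credibleInterval
#' @export
setMethod("credibleInterval", "ZetaPosterior", function(x) x@cri)

#' @rdname credibleInterval
#' @export
setMethod("credibleInterval", "SteadyState", function(x) x@meanHeightCI)

#' @rdname transitionCounts
#' @export
setMethod("transitionCounts", "TransitionModel", function(x) x@counts)

#' @rdname classEdges
#' @export
setMethod("classEdges", "TransitionModel", function(x) x@edges)

#' @rdname classEdges
#' @export
setMethod("classEdges", "SteadyState", function(x) x@edges)

#' @rdname stationaryDistribution
#' @export
setMethod("stationaryDistribution", "SteadyState", function(x) x@distribution)

#' @rdname meanCanopyHeight
#' @export
setMethod("meanCanopyHeight", "SteadyState", function(x) x@meanHeight)

#' @rdname endmemberSpectra
#' @export
setMethod("endmemberSpectra", "EndmemberSet", function(x) x@spectra)

#' @rdname fractionValues
#' @export
setMethod("fractionValues", "FractionMap", function(x) x@fractions)
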