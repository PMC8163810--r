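#' @include AllGenerics.R
NULL

#' Grid value matrix of a raster layer
#'
#' Accessor for the numeric value grid of any raster-like object. Values are
#' returned as a matrix whose first row is the northernmost row of pixels
#' (map orientation); nodata pixels are `NA`.
#'
#' @param x a raster-like object (e.g. [GridLayer-class]).
#' @return numeric matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Pixel resolution in metres
#' @param x a raster-like object.
#' @return scalar numeric, pixel edge length (m).
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))

#' Planar origin (lower-left corner) of a raster grid
#' @param x a raster-like object.
#' @return numeric length-2, `c(xmin, ymin)` in metres.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' Extent of a raster grid
#' @param x a raster-like object.
#' @return numeric length-4, `c(xmin, xmax, ymin, ymax)` in metres.
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' Coordinate reference system label carried by a grid
#'
#' The CRS is carried as free-text metadata (e.g. `"EPSG:32616"`) and is not
#' validated against any authority database.
#'
#' @param x a raster-like object.
#' @return character scalar (possibly `NA`).
#' @export
setGeneric("gridCRS", function(x) standardGeneric("gridCRS"))

#' Posterior chain of retained MCMC samples
#' @param x a [ZetaPosterior-class] object.
#' @return numeric vector of retained exponent samples.
#' @export
setGeneric("posteriorChain", function(x) standardGeneric("posteriorChain"))

#' Posterior median of the power-law exponent
#' @param x a [ZetaPosterior-class] object.
#' @return scalar numeric.
#' @export
setGeneric("lambdaMedian", function(x) standardGeneric("lambdaMedian"))

#' 95\% credible interval
#' @param x a posterior summary object.
#' @return numeric length-2, `c(low, high)`.
#' @export
setGeneric("credibleInterval", function(x) standardGeneric("credibleInterval"))

#' Height-class transition count matrix
#'
#' Entry `[i, j]` is the number of pixels starting in height class `j` and
#' ending in height class `i`.
#'
#' @param x a [TransitionModel-class] object.
#' @return integer matrix.
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' Height class bin edges (m)
#' @param x a [TransitionModel-class] or [SteadyState-class] object.
#' @return numeric vector of class edges, `0:nClasses` times the class width.
#' @export
setGeneric("classEdges", function(x) standardGeneric("classEdges"))

#' Stationary (projected equilibrium) height distribution
#' @param x a [SteadyState-class] object.
#' @return numeric probability vector over height classes (sums to 1).
#' @export
setGeneric("stationaryDistribution",
           function(x) standardGeneric("stationaryDistribution"))

#' Mean of a projected height distribution (m)
#' @param x a [SteadyState-class] object.
#' @return scalar numeric, metres.
#' @export
setGeneric("meanCanopyHeight", function(x) standardGeneric("meanCanopyHeight"))

#' Endmember reflectance spectra
#' @param x an [EndmemberSet-class] object.
#' @return numeric matrix, bands in rows, endmembers in columns.
#' @export
setGeneric("endmemberSpectra", function(x) standardGeneric("endmemberSpectra"))

#' Per-pixel endmember fraction array
#' @param x a [FractionMap-class] object.
#' @return numeric array `[rows, cols, endmembers]`.
#' @export
setGeneric("fractionValues", function(x) standardGeneric("fractionValues"))
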