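#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Raster geometry and layers
## ---------------------------------------------------------------------------

#' Virtual base class for gridded planar data
#'
#' Carries the geometry shared by all raster-like classes: square pixel size,
#' planar origin of the lower-left corner, and a free-text CRS label. Pixel
#' footprints are half-open, `[x0, x0 + res) x [y0, y0 + res)`, so every point
#' belongs to exactly one pixel.
#'
#' @slot resolution numeric scalar, pixel edge length (m), > 0.
#' @slot origin numeric length-2, `c(xmin, ymin)` of the grid corner (m).
#' @slot crs character scalar CRS label (metadata only, may be `NA`).
#' @name RasterGeometry-class
#' @exportClass RasterGeometry
setClass("RasterGeometry",
         representation("VIRTUAL",
                        resolution = "numeric",
                        origin = "numeric",
                        crs = "character"),
         prototype(resolution = 1, origin = c(0, 0), crs = NA_character_),
         validity = function(object) {
           if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
               object@resolution <= 0)
             return("resolution must be a single finite value > 0")
           if (length(object@origin) != 2L || any(!is.finite(object@origin)))
             return("origin must be two finite coordinates")
           if (length(object@crs) != 1L)
             return("crs must be a single character label")
           TRUE
         })

#' Single-band raster layer
#'
#' A numeric grid in map orientation: row 1 is the northernmost row of pixels,
#' column 1 the westernmost. Nodata pixels are stored as `NA` internally and
#' written as -9999 on disk (see [writeAsciiGrid()]).
#'
#' @slot values numeric matrix of pixel values.
#' @seealso [HeightRaster-class], [heightChange()]
#' @name GridLayer-class
#' @exportClass GridLayer
setClass("GridLayer",
         contains = "RasterGeometry",
         representation(values = "matrix"),
         validity = function(object) {
           if (!is.numeric(object@values))
             return("values must be a numeric matrix")
           if (any(dim(object@values) < 1L))
             return("values must have at least one row and one column")
           TRUE
         })

#' Canopy height raster
#'
#' A [GridLayer-class] whose values are canopy height above ground in metres.
#' Heights are non-negative (negative heights are clamped to 0 at
#' construction time by the rasterization functions); nodata is `NA`.
#'
#' @seealso [rasterizeTIN()], [rasterizeMean()], [generateCHM()]
#' @name HeightRaster-class
#' @exportClass HeightRaster
setClass("HeightRaster",
         contains = "GridLayer",
         validity = function(object) {
           v <- object@values
           if (any(v < -1e-9, na.rm = TRUE))
             return("canopy heights must be >= 0 (or NA for nodata)")
           TRUE
         })

#' Canopy height change raster
#'
#' Per-pixel final-minus-initial canopy height (m). Defined only where both
#' epochs have data; values may be negative. Produced by [heightChange()].
#'
#' @name HeightChangeRaster-class
#' @exportClass HeightChangeRaster
setClass("HeightChangeRaster", contains = "GridLayer")

#' Multi-band raster (reflectance stack)
#'
#' @slot values numeric array `[rows, cols, bands]`, map orientation as in
#'   [GridLayer-class].
#' @slot bandNames character vector of band labels.
#' @name BandRaster-class
#' @exportClass BandRaster
setClass("BandRaster",
         contains = "RasterGeometry",
         representation(values = "array", bandNames = "character"),
         validity = function(object) {
           d <- dim(object@values)
           if (length(d) != 3L)
             return("values must be a 3-d array [rows, cols, bands]")
           if (length(object@bandNames) != d[3L])
             return("bandNames length must equal the number of bands")
           TRUE
         })

## ---------------------------------------------------------------------------
## Gap analysis
## ---------------------------------------------------------------------------

#' Labeled canopy gap map
#'
#' Connected components (8-connectivity, diagonals included) of the pixel set
#' with canopy height at or below a threshold. Label 0 is non-gap; labels
#' 1..n identify maximal gaps.
#'
#' @slot labels integer matrix of component labels (map orientation).
#' @slot threshold numeric, height cutoff defining gaps (m).
#' @slot connectivity integer, always 8.
#' @seealso [labelGaps()], [gapSizes()]
#' @name GapLabelMap-class
#' @exportClass GapLabelMap
setClass("GapLabelMap",
         contains = "RasterGeometry",
         representation(labels = "matrix",
                        threshold = "numeric",
                        connectivity = "integer"),
         prototype(connectivity = 8L),
         validity = function(object) {
           if (!is.numeric(object@labels))
             return("labels must be an integer matrix")
           if (any(object@labels < 0, na.rm = TRUE))
             return("labels must be >= 0")
           if (!identical(object@connectivity, 8L))
             return("connectivity is fixed at 8 (diagonals included)")
           if (length(object@threshold) != 1L || object@threshold < 0)
             return("threshold must be a single value >= 0")
           TRUE
         })

#' Posterior for the Zeta (discrete power law) exponent
#'
#' Result of Metropolis-Hastings sampling of the gap size-frequency exponent.
#' The retained chain has exactly `(nTotal - nBurnin) / thin` samples, all
#' inside the uniform prior support.
#'
#' @slot chain numeric vector of retained samples (after burn-in + thinning).
#' @slot lambdaMedian numeric, posterior median.
#' @slot cri numeric length-2, central 95\% credible interval.
#' @slot settings list with `nTotal`, `nBurnin`, `thin`, `priorMin`,
#'   `priorMax`, `proposalSd`, `seed`.
#' @slot nSizes integer, number of gap sizes in the likelihood.
#' @slot acceptanceRate numeric, fraction of accepted proposals.
#' @seealso [estimateLambda()], [compareLambda()]
#' @name ZetaPosterior-class
#' @exportClass ZetaPosterior
setClass("ZetaPosterior",
         representation(chain = "numeric",
                        lambdaMedian = "numeric",
                        cri = "numeric",
                        settings = "list",
                        nSizes = "integer",
                        acceptanceRate = "numeric"),
         validity = function(object) {
           s <- object@settings
           need <- c("nTotal", "nBurnin", "thin", "priorMin", "priorMax",
                     "proposalSd", "seed")
           if (!all(need %in% names(s)))
             return(paste("settings must contain:", paste(need, collapse = ", ")))
           expected <- (s$nTotal - s$nBurnin) / s$thin
           if (length(object@chain) != expected)
             return(sprintf("retained chain length %d != (nTotal - nBurnin)/thin = %g",
                            length(object@chain), expected))
           if (any(object@chain < s$priorMin - 1e-12) ||
               any(object@chain > s$priorMax + 1e-12))
             return("retained samples fall outside the prior support")
           if (length(object@cri) != 2L || object@cri[1] > object@cri[2])
             return("cri must be c(low, high) with low <= high")
           if (object@lambdaMedian < object@cri[1] ||
               object@lambdaMedian > object@cri[2])
             return("posterior median must lie inside the credible interval")
           TRUE
         })

## ---------------------------------------------------------------------------
## Allometry / carbon
## ---------------------------------------------------------------------------

#' Fitted TCH-to-AGBD power allometry
#'
#' Gaussian maximum-likelihood fit of `AGBD = a * TCH^b` with additive
#' normal residuals on the biomass scale.
#'
#' @slot a numeric, coefficient (> 0).
#' @slot b numeric, exponent.
#' @slot sigma numeric, ML residual standard deviation (Mg ha^-1).
#' @slot r2 numeric, 1 - SSE/SST.
#' @slot rmsePct numeric, RMSE as a percentage of mean observed AGBD.
#' @slot n integer, number of plots.
#' @slot vcov numeric 2x2 matrix, asymptotic covariance of `(log a, b)`.
#' @slot plotData data.frame of the observations used in the fit.
#' @seealso [fitAllometry()], [predictAGBD()], [monteCarloACD()]
#' @name AllometricFit-class
#' @exportClass AllometricFit
setClass("AllometricFit",
         representation(a = "numeric", b = "numeric", sigma = "numeric",
                        r2 = "numeric", rmsePct = "numeric", n = "integer",
                        vcov = "matrix", plotData = "data.frame"),
         validity = function(object) {
           if (object@a <= 0) return("a must be > 0")
           if (object@sigma < 0) return("sigma must be >= 0")
           if (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)
             return("r2 must lie in [0, 1]")
           if (!all(dim(object@vcov) == c(2L, 2L)))
             return("vcov must be 2x2 (log a, b)")
           TRUE
         })

#' Aboveground carbon density map with Monte Carlo bounds
#'
#' ACD (Mg C ha^-1) on the 0.5-ha analysis grid. `values` is the noise-free
#' prediction from the fitted allometry times the carbon fraction; `ciLow` and
#' `ciHigh` are per-cell 2.5/97.5 Monte Carlo percentiles. The full landscape
#' draw vector is retained so that paired differencing of two epochs is exact.
#'
#' @slot values,ciLow,ciHigh numeric matrices (map orientation).
#' @slot carbonFraction numeric scalar (default 0.47).
#' @slot cellDraws numeric array `[rows, cols, nDraws]` of ACD draws.
#' @slot landscapeDraws numeric vector of landscape-mean ACD per draw.
#' @slot landscapeCI numeric length-2, 95\% CI of landscape-mean ACD.
#' @slot settings list: `nDraws`, `seed`, `residualSeed`, `perturbParams`,
#'   and the fit parameters used (`a`, `b`, `sigma`).
#' @seealso [monteCarloACD()], [acdChange()]
#' @name AcdMap-class
#' @exportClass AcdMap
setClass("AcdMap",
         contains = "RasterGeometry",
         representation(values = "matrix", ciLow = "matrix", ciHigh = "matrix",
                        carbonFraction = "numeric", cellDraws = "array",
                        landscapeDraws = "numeric", landscapeCI = "numeric",
                        settings = "list"),
         validity = function(object) {
           if (!all(dim(object@ciLow) == dim(object@values)) ||
               !all(dim(object@ciHigh) == dim(object@values)))
             return("ciLow/ciHigh must match the dimensions of values")
           if (any(object@values < -1e-9, na.rm = TRUE))
             return("ACD must be >= 0")
           if (any(object@ciLow > object@ciHigh + 1e-9, na.rm = TRUE))
             return("ciLow must be <= ciHigh cell-wise")
           if (object@carbonFraction <= 0 || object@carbonFraction > 1)
             return("carbonFraction must be in (0, 1]")
           TRUE
         })

## ---------------------------------------------------------------------------
## Height transitions
## ---------------------------------------------------------------------------

#' Canopy height-class transition model
#'
#' Square count matrix over 1-m (by default) height classes. Class `c` covers
#' heights `[c-1, c)` m, except that heights exactly at the top edge fall in
#' the last class. Entry `[i, j]` counts pixels starting in class `j` and
#' ending in class `i` over the observation interval.
#'
#' @slot counts numeric matrix of non-negative integer counts.
#' @slot classWidth numeric, class width (m).
#' @slot nClasses integer, number of classes (>= 2).
#' @slot edges numeric, class edges `(0, w, 2w, ..., nClasses * w)`.
#' @seealso [buildTransitionMatrix()], [steadyState()]
#' @name TransitionModel-class
#' @exportClass TransitionModel
setClass("TransitionModel",
         representation(counts = "matrix", classWidth = "numeric",
                        nClasses = "integer", edges = "numeric"),
         validity = function(object) {
           cm <- object@counts
           if (nrow(cm) != ncol(cm)) return("counts must be square")
           if (object@nClasses < 2L) return("need at least 2 height classes")
           if (nrow(cm) != object@nClasses)
             return("counts dimension must equal nClasses")
           if (any(cm < 0) || any(abs(cm - round(cm)) > 1e-9))
             return("counts must be non-negative integers")
           if (length(object@edges) != object@nClasses + 1L)
             return("edges must have nClasses + 1 entries")
           TRUE
         })

#' Projected steady-state canopy height distribution
#'
#' The dominant right eigenvector of the column-stochastic height transition
#' matrix, normalized to a probability vector, with (optionally) a
#' Dirichlet-multinomial posterior envelope.
#'
#' @slot distribution numeric probability vector over height classes.
#' @slot meanHeight numeric, mean height (m) using class midpoints.
#' @slot envLow,envHigh numeric, per-class 95\% credible bounds (length 0 for
#'   a point estimate without posterior).
#' @slot meanHeightCI numeric length-2 (or length 0), 95\% CI of the mean.
#' @slot nDraws integer, number of posterior draws (0 for point estimate).
#' @slot seed integer seed used for posterior draws (NA for point estimate).
#' @slot edges numeric class edges as in [TransitionModel-class].
#' @seealso [steadyState()], [steadyStatePosterior()]
#' @name SteadyState-class
#' @exportClass SteadyState
setClass("SteadyState",
         representation(distribution = "numeric", meanHeight = "numeric",
                        envLow = "numeric", envHigh = "numeric",
                        meanHeightCI = "numeric", nDraws = "integer",
                        seed = "integer", edges = "numeric"),
         validity = function(object) {
           p <- object@distribution
           if (any(p < -1e-12)) return("distribution entries must be >= 0")
           if (abs(sum(p) - 1) > 1e-12)
             return("distribution must sum to 1 within 1e-12")
           ne <- length(object@envLow)
           if (ne != length(object@envHigh))
             return("envLow and envHigh must have equal length")
           if (ne > 0 && ne != length(p))
             return("envelope length must equal the number of classes")
           TRUE
         })

## ---------------------------------------------------------------------------
## Spectral mixture analysis
## ---------------------------------------------------------------------------

#' Endmember spectra for spectral mixture analysis
#'
#' @slot spectra numeric matrix, reflectance with bands in rows and
#'   endmembers in columns (column names are endmember names, conventionally
#'   `PV`, `NPV`, `shade`).
#' @slot bands character vector of band labels.
#' @seealso [endmemberSet()], [unmix()]
#' @name EndmemberSet-class
#' @exportClass EndmemberSet
setClass("EndmemberSet",
         representation(spectra = "matrix", bands = "character"),
         validity = function(object) {
           sp <- object@spectra
           if (nrow(sp) < 2L) return("need at least 2 bands")
           if (is.null(colnames(sp))) return("spectra columns must be named")
           if (any(sp < 0) || any(sp > 1))
             return("reflectance values must lie in [0, 1]")
           if (qr(sp)$rank < ncol(sp))
             return("endmember spectra must be linearly independent")
           if (length(object@bands) != nrow(sp))
             return("bands length must equal the number of spectral bands")
           TRUE
         })

#' Per-pixel endmember fraction map
#'
#' Result of sum-to-one constrained linear unmixing. Fractions sum to one per
#' pixel (to solver tolerance); negative fractions are permitted (the
#' constraint set matches classic sum-to-one linear SMA without a
#' non-negativity constraint).
#'
#' @slot fractions numeric array `[rows, cols, endmembers]`.
#' @slot rms numeric matrix of per-pixel residual RMS reflectance.
#' @slot endmemberNames character vector.
#' @seealso [unmix()], [deltaNPV()]
#' @name FractionMap-class
#' @exportClass FractionMap
setClass("FractionMap",
         contains = "RasterGeometry",
         representation(fractions = "array", rms = "matrix",
                        endmemberNames = "character"),
         validity = function(object) {
           d <- dim(object@fractions)
           if (length(d) != 3L)
             return("fractions must be [rows, cols, endmembers]")
           if (length(object@endmemberNames) != d[3L])
             return("endmemberNames length must match the fraction array")
           sums <- apply(object@fractions, c(1, 2), sum)
           if (any(abs(sums - 1) > 1e-9, na.rm = TRUE))
             return("fractions must sum to 1 per pixel within 1e-9")
           if (any(object@rms < -1e-12, na.rm = TRUE))
             return("residual RMS must be >= 0")
           TRUE
         })

## ---------------------------------------------------------------------------
## Recovery bookkeeping
## ---------------------------------------------------------------------------

#' Carbon recovery scenario
#'
#' Inputs for the bookkeeping estimate of the time needed to regrow the
#' carbon lost to a disturbance: the mean landscape ACD loss, a long-term
#' annual gain, an optional initial fast phase of elevated annual gains, and
#' the parameters of the pre-event baseline adjustment (extrapolating carbon
#' accumulation between the reference survey and the event).
#'
#' @slot acdLoss numeric, mean landscape ACD loss (Mg C ha^-1), >= 0.
#' @slot longTermGain numeric, long-term annual ACD gain (Mg C ha^-1 yr^-1).
#' @slot elevatedGains numeric vector, annual gains for the initial fast
#'   phase (Mg C ha^-1 yr^-1); its length is the phase duration in years.
#' @slot baselineAdjustGain numeric, annual gain used to extrapolate the
#'   pre-event baseline (Mg C ha^-1 yr^-1).
#' @slot baselineAdjustYears numeric, years between reference map and event.
#' @seealso [recoveryScenario()], [recoveryTimeLongTerm()],
#'   [recoveryTimeTwoPhase()], [adjustBaseline()]
#' @name RecoveryScenario-class
#' @exportClass RecoveryScenario
setClass("RecoveryScenario",
         representation(acdLoss = "numeric", longTermGain = "numeric",
                        elevatedGains = "numeric",
                        baselineAdjustGain = "numeric",
                        baselineAdjustYears = "numeric"),
         validity = function(object) {
           if (object@acdLoss < 0) return("acdLoss must be >= 0")
           if (object@longTermGain < 0) return("longTermGain must be >= 0")
           if (any(object@elevatedGains < 0))
             return("elevated gains must be >= 0")
           if (object@baselineAdjustGain < 0 || object@baselineAdjustYears < 0)
             return("baseline adjustment parameters must be >= 0")
           TRUE
         })

## ---------------------------------------------------------------------------
## Synthetic-data configs
## ---------------------------------------------------------------------------

#' Configuration for the synthetic forest landscape generator
#'
#' @slot extentM numeric, width/height of the square landscape (m).
#' @slot chmResolutionM numeric, CHM pixel size (m), default 1.25.
#' @slot meanCanopyHeightM numeric, baseline canopy height (m).
#' @slot heightSdM numeric, spatial standard deviation of height (m).
#' @slot gapLambda numeric, Zeta exponent of generated gap sizes (> 1).
#' @slot nGaps integer, number of gaps to carve (>= 0).
#' @slot gapFloorHeightM numeric, height assigned inside gaps (m, >= 0).
#' @slot smoothWidthPx integer, moving-average width (pixels) used to impose
#'   spatial autocorrelation on the background height field.
#' @slot seed integer RNG seed.
#' @seealso [syntheticForestConfig()], [generateCHM()]
#' @name SyntheticForestConfig-class
#' @exportClass SyntheticForestConfig
setClass("SyntheticForestConfig",
         representation(extentM = "numeric", chmResolutionM = "numeric",
                        meanCanopyHeightM = "numeric", heightSdM = "numeric",
                        gapLambda = "numeric", nGaps = "integer",
                        gapFloorHeightM = "numeric", smoothWidthPx = "integer",
                        seed = "integer"),
         validity = function(object) {
           if (object@extentM <= 0) return("extentM must be > 0")
           if (object@chmResolutionM <= 0) return("chmResolutionM must be > 0")
           if (object@gapLambda <= 1) return("gapLambda must be > 1")
           if (object@nGaps < 0L) return("nGaps must be >= 0")
           if (object@gapFloorHeightM < 0) return("gapFloorHeightM must be >= 0")
           if (object@heightSdM < 0) return("heightSdM must be >= 0")
           if (object@smoothWidthPx < 1L) return("smoothWidthPx must be >= 1")
           TRUE
         })

#' Configuration for simulated allometry calibration plots
#'
#' @slot aTrue numeric, true allometric coefficient (> 0).
#' @slot bTrue numeric, true allometric exponent.
#' @slot residualSd numeric, Gaussian noise s.d. on AGBD (Mg ha^-1, >= 0).
#' @slot nPlots integer, number of plots (>= 3; default 18, the size of a
#'   typical long-term inventory calibration set).
#' @slot tchRange numeric length-2, range of plot TCH (m).
#' @slot seed integer RNG seed.
#' @seealso [allometrySimConfig()], [generatePlots()]
#' @name AllometrySimConfig-class
#' @exportClass AllometrySimConfig
setClass("AllometrySimConfig",
         representation(aTrue = "numeric", bTrue = "numeric",
                        residualSd = "numeric", nPlots = "integer",
                        tchRange = "numeric", seed = "integer"),
         validity = function(object) {
           if (object@aTrue <= 0) return("aTrue must be > 0")
           if (object@nPlots < 3L) return("nPlots must be >= 3")
           if (object@residualSd < 0) return("residualSd must be >= 0")
           if (length(object@tchRange) != 2L ||
               object@tchRange[1] <= 0 ||
               object@tchRange[2] <= object@tchRange[1])
             return("tchRange must be c(min, max) with 0 < min < max")
           TRUE
         })
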