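#' @include raster-grid.R
NULL

#' Configuration for the synthetic forest landscape generator
#'
#' Bundles the parameters of [generateCHM()]: a square landscape of smoothly
#' varying canopy height into which power-law-sized gaps are carved. Defaults
#' emulate an old tropical lowland forest: 22 m mean canopy height with 5 m
#' spatial variation at the native 1.25 m canopy-height-model resolution, and
#' a gap size-frequency exponent of 2.3 (gap sizes in pixels), in the range
#' reported for undisturbed neotropical canopies.
#'
#' @param extentM width/height of the square landscape (m).
#' @param chmResolutionM pixel size (m); 1.25 m matches the native grid used
#'   for gap delineation.
#' @param meanCanopyHeightM baseline canopy height (m).
#' @param heightSdM spatial standard deviation of canopy height (m).
#' @param gapLambda Zeta exponent of carved gap sizes (> 1).
#' @param nGaps number of gaps to carve (>= 0).
#' @param gapFloorHeightM height assigned inside carved gaps (m).
#' @param smoothWidthPx width (pixels) of the moving-average filter imposing
#'   spatial autocorrelation on the background height field.
#' @param seed RNG seed; all randomness in [generateCHM()] flows from it.
#' @return a validated [SyntheticForestConfig-class].
#' @export
syntheticForestConfig <- function(extentM = 210, chmResolutionM = 1.25,
                                  meanCanopyHeightM = 22, heightSdM = 5,
                                  gapLambda = 2.3, nGaps = 150L,
                                  gapFloorHeightM = 0.5, smoothWidthPx = 7L,
                                  seed = 1L) {
  new("SyntheticForestConfig", extentM = extentM,
      chmResolutionM = chmResolutionM, meanCanopyHeightM = meanCanopyHeightM,
      heightSdM = heightSdM, gapLambda = gapLambda, nGaps = as.integer(nGaps),
      gapFloorHeightM = gapFloorHeightM,
      smoothWidthPx = as.integer(smoothWidthPx), seed = as.integer(seed))
}

#' Configuration for simulated allometry calibration plots
#'
#' Defaults produce 18 half-hectare plots (the size of a typical long-term
#' inventory calibration network) whose AGBD follows
#' `a * TCH^b` with additive Gaussian noise. The default coefficients give
#' ~190 Mg ha^-1 at 22 m TCH, and the default residual standard deviation of
#' 18 Mg ha^-1 (~9\% of mean AGBD) matches the fit quality that lidar
#' allometries typically achieve at this plot size.
#'
#' @param aTrue true allometric coefficient (> 0).
#' @param bTrue true allometric exponent.
#' @param residualSd Gaussian noise on AGBD (Mg ha^-1).
#' @param nPlots number of plots (>= 3).
#' @param tchRange `c(min, max)` plot TCH range (m).
#' @param seed RNG seed.
#' @return a validated [AllometrySimConfig-class].
#' @export
allometrySimConfig <- function(aTrue = 3.8, bTrue = 1.27, residualSd = 18,
                               nPlots = 18L, tchRange = c(12, 32), seed = 1L) {
  new("AllometrySimConfig", aTrue = aTrue, bTrue = bTrue,
      residualSd = residualSd, nPlots = as.integer(nPlots),
      tchRange = tchRange, seed = as.integer(seed))
}

#' Sample from the Zeta (discrete power law) distribution
#'
#' Inverse-CDF sampling on a precomputed cumulative table over
#' `k = 1..kMax`, with the (tiny, for exponents > 1.01) tail mass beyond
#' `kMax` assigned to `kMax`. The pmf is `f(k) = k^-lambda / zeta(lambda)`.
#'
#' @param n number of samples.
#' @param lambda exponent (> 1).
#' @param kMax table truncation point (default 1e6).
#' @param seed RNG seed, or `NULL` to draw from the current RNG stream.
#' @return integer vector of sizes >= 1.
#' @seealso [zetaLogPMF()], [estimateLambda()]
#' @export
sampleZeta <- function(n, lambda, kMax = 1e6, seed = NULL) {
  if (lambda <= 1) stop("lambda must be > 1", call. = FALSE)
  if (n == 0L) return(integer(0))
  k <- seq_len(kMax)
  cum <- cumsum(k^(-lambda)) / pracma::zeta(lambda)
  cum[kMax] <- 1  # truncation: tail mass beyond kMax goes to kMax
  draw <- function() {
    u <- stats::runif(n)
    as.integer(findInterval(u, cum) + 1L)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

## internal: separable moving-average smoother with edge replication
boxSmooth <- function(m, width) {
  if (width <= 1L) return(m)
  half <- width %/% 2
  smooth1 <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
    cs <- cumsum(padded)
    (cs[(width):length(padded)] -
       c(0, cs[seq_len(length(padded) - width)])) / width
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

## internal: the k grid pixels nearest to (row0, col0) on an nr x nc grid —
## a rasterized disk with exactly k pixels (fewer only if the clipped
## window runs out). Ties break deterministically by row then column.
diskPixels <- function(k, row0, col0, nr, nc) {
  w <- max(1L, as.integer(ceiling(sqrt(k / pi))) + 1L)
  repeat {
    rows <- max(1L, row0 - w):min(nr, row0 + w)
    cols <- max(1L, col0 - w):min(nc, col0 + w)
    if (length(rows) * length(cols) >= k ||
        (length(rows) == nr && length(cols) == nc)) break
    w <- w * 2L
  }
  rc <- expand.grid(row = rows, col = cols)
  d2 <- (rc$row - row0)^2 + (rc$col - col0)^2
  ord <- order(d2, rc$row, rc$col)
  rc[ord[seq_len(min(k, nrow(rc)))], , drop = FALSE]
}

#' Generate a synthetic canopy height model
#'
#' Builds a gap-free background canopy as spatially smoothed Gaussian noise
#' (moving-average smoothing of white noise, rescaled to the requested mean
#' and standard deviation, truncated at zero) and then carves `nGaps`
#' disk-shaped gaps whose pixel areas are drawn from a Zeta distribution with
#' exponent `gapLambda`. Overlapping gaps merge (later carving wins), as
#' coalescing real-world gaps do. The raster has no nodata pixels.
#'
#' @param config a [SyntheticForestConfig-class].
#' @return a [HeightRaster-class].
#' @examples
#' chm <- generateCHM(syntheticForestConfig(extentM = 60, nGaps = 10, seed = 7))
#' chm
#' @export
generateCHM <- function(config) {
  methods::validObject(config)
  res <- config@chmResolutionM
  n <- round(config@extentM / res)
  if (n < 2) stop("extent too small for the requested resolution", call. = FALSE)
  withSeed(config@seed, {
    noise <- matrix(stats::rnorm(n * n), n, n)
    sm <- boxSmooth(noise, config@smoothWidthPx)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    v <- pmax(config@meanCanopyHeightM + config@heightSdM * sm, 0)
    if (config@nGaps > 0L) {
      sizes <- sampleZeta(config@nGaps, config@gapLambda)
      if (max(sizes) > n * n ||
          2 * sqrt(max(sizes) / pi) > n)
        stop(sprintf("largest sampled gap (%d px) exceeds the raster",
                     max(sizes)), call. = FALSE)
      ctrRow <- sample.int(n, config@nGaps, replace = TRUE)
      ctrCol <- sample.int(n, config@nGaps, replace = TRUE)
      for (g in seq_len(config@nGaps)) {
        px <- diskPixels(sizes[g], ctrRow[g], ctrCol[g], n, n)
        v[cbind(px$row, px$col)] <- config@gapFloorHeightM
      }
    }
    heightRaster(v, resolution = res, origin = c(0, 0))
  })
}

#' Carve a synthetic blowdown into a canopy height model
#'
#' Lowers additional power-law-sized disk patches to near-ground height until
#' approximately `severity` of the total canopy volume (summed pixel height)
#' has been removed. Candidate patches that would overshoot the target by
#' more than ~4.5\% of total volume are rejected and redrawn, so the realized
#' removed fraction lies within about 0.05 of `severity`. The true per-pixel
#' change is returned alongside the disturbed raster for use as a test
#' oracle.
#'
#' @param chm a [HeightRaster-class] (no nodata).
#' @param severity fraction of total canopy volume to remove, in `[0, 1]`.
#' @param gapLambdaPost Zeta exponent of the carved patch sizes; disturbance
#'   shifts the size-frequency distribution towards large gaps, so this is
#'   typically smaller than the pre-disturbance exponent.
#' @param gapFloorHeightM height assigned inside carved patches (m).
#' @param seed RNG seed.
#' @return a list with elements `chm` (the disturbed [HeightRaster-class]),
#'   `trueChange` (a [HeightChangeRaster-class], post minus pre) and
#'   `removedFraction` (realized fraction of canopy volume removed).
#' @export
applyBlowdown <- function(chm, severity, gapLambdaPost = 1.7,
                          gapFloorHeightM = 0.3, seed = 1L) {
  if (severity < 0 || severity > 1)
    stop("severity must be in [0, 1]", call. = FALSE)
  v <- gridValues(chm)
  if (any(is.na(v))) stop("chm must have no nodata pixels", call. = FALSE)
  nr <- nrow(v); nc <- ncol(v)
  total <- sum(v)
  target <- severity * total
  removed <- 0
  if (severity > 0 && total > 0) {
    withSeed(seed, {
      tries <- 0L
      while (removed < target) {
        k <- if (tries > 500L) 1L else sampleZeta(1L, gapLambdaPost)
        row0 <- sample.int(nr, 1L); col0 <- sample.int(nc, 1L)
        px <- diskPixels(k, row0, col0, nr, nc)
        idx <- cbind(px$row, px$col)
        vol <- sum(pmax(v[idx] - gapFloorHeightM, 0))
        if (removed + vol > target + 0.045 * total && tries <= 500L) {
          tries <- tries + 1L
          next
        }
        v[idx] <- pmin(v[idx], gapFloorHeightM)
        removed <- removed + vol
      }
    })
  }
  post <- heightRaster(v, resolution = gridResolution(chm),
                       origin = gridOrigin(chm), crs = gridCRS(chm))
  change <- new("HeightChangeRaster", values = v - gridValues(chm),
                resolution = gridResolution(chm), origin = gridOrigin(chm),
                crs = gridCRS(chm))
  list(chm = post, trueChange = change,
       removedFraction = if (total > 0) removed / total else 0)
}

#' Simulate allometry calibration plots
#'
#' Plot TCH is uniform over `tchRange`; AGBD is `a * TCH^b` plus Gaussian
#' noise, truncated at zero.
#'
#' @param config an [AllometrySimConfig-class].
#' @return data.frame with columns `plot_id`, `tch_m`, `agbd_mg_ha`.
#' @seealso [fitAllometry()]
#' @export
generatePlots <- function(config) {
  methods::validObject(config)
  withSeed(config@seed, {
    tch <- stats::runif(config@nPlots, config@tchRange[1], config@tchRange[2])
    agbd <- pmax(config@aTrue * tch^config@bTrue +
                   stats::rnorm(config@nPlots, 0, config@residualSd), 0)
    data.frame(plot_id = sprintf("P%02d", seq_len(config@nPlots)),
               tch_m = tch, agbd_mg_ha = agbd)
  })
}

#' Construct an endmember set
#'
#' With no arguments, returns the package's synthetic three-endmember set
#' (photosynthetic vegetation, non-photosynthetic vegetation, shade) over six
#' reflective bands with the qualitative shapes of those spectra: PV with a
#' strong near-infrared plateau, NPV with elevated shortwave-infrared
#' reflectance from exposed dead wood, and a dark shade endmember.
#'
#' @param spectra optional numeric matrix, bands x endmembers, values in
#'   `[0, 1]`, with named columns.
#' @param bands optional character vector of band labels.
#' @return an [EndmemberSet-class].
#' @export
endmemberSet <- function(spectra = NULL, bands = NULL) {
  if (is.null(spectra)) {
    bands <- c("blue", "green", "red", "nir", "swir1", "swir2")
    spectra <- cbind(PV    = c(0.02, 0.05, 0.03, 0.45, 0.18, 0.08),
                     NPV   = c(0.08, 0.12, 0.18, 0.30, 0.42, 0.35),
                     shade = c(0.01, 0.01, 0.01, 0.02, 0.01, 0.01))
    rownames(spectra) <- bands
  }
  if (is.null(bands)) {
    bands <- rownames(spectra)
    if (is.null(bands)) bands <- sprintf("band%d", seq_len(nrow(spectra)))
  }
  new("EndmemberSet", spectra = spectra, bands = bands)
}

#' Generate mixed reflectance pixels from endmember fractions
#'
#' Per-pixel reflectance is the fraction-weighted sum of the endmember
#' spectra plus optional Gaussian noise: the forward model inverted by
#' [unmix()].
#'
#' @param fractions numeric array `[rows, cols, endmembers]`; each pixel's
#'   fractions must be >= 0 and sum to 1 within 1e-9.
#' @param endmembers an [EndmemberSet-class].
#' @param noiseSd Gaussian noise standard deviation (reflectance units).
#' @param seed RNG seed (ignored when `noiseSd` is 0).
#' @param resolutionM pixel size of the output raster (m).
#' @param origin grid origin `c(xmin, ymin)`.
#' @return a [BandRaster-class].
#' @export
generateMixedPixels <- function(fractions, endmembers, noiseSd = 0, seed = 1L,
                                resolutionM = 30, origin = c(0, 0)) {
  d <- dim(fractions)
  sp <- endmemberSpectra(endmembers)
  if (length(d) != 3L || d[3] != ncol(sp))
    stop("fractions must be [rows, cols, ", ncol(sp), " endmembers]",
         call. = FALSE)
  fm <- matrix(fractions, d[1] * d[2], d[3])
  if (any(fm < -1e-12))
    stop("endmember fractions must be >= 0", call. = FALSE)
  if (any(abs(rowSums(fm) - 1) > 1e-9))
    stop("endmember fractions must sum to 1 within 1e-9 on every pixel",
         call. = FALSE)
  refl <- fm %*% t(sp)                      # pixels x bands
  if (noiseSd > 0)
    refl <- refl + withSeed(seed, matrix(stats::rnorm(length(refl), 0, noiseSd),
                                         nrow(refl)))
  arr <- array(refl, c(d[1], d[2], nrow(sp)))
  new("BandRaster", values = arr, bandNames = endmembers@bands,
      resolution = resolutionM, origin = origin, crs = NA_character_)
}
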