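#' @include raster-grid.R
NULL

#' Linear spectral mixture analysis with a sum-to-one constraint
#'
#' Solves, for every pixel, the equality-constrained least-squares problem
#' `min || E f - r ||` subject to `sum(f) = 1`, where `E` holds the
#' endmember spectra in columns and `r` is the pixel reflectance. The
#' constraint is enforced exactly through the KKT system; fractions are not
#' constrained to be non-negative (matching classic sum-to-one linear SMA),
#' and pixels with any negative fraction are counted in a message.
#'
#' @param reflectance a [BandRaster-class] whose bands match the endmember
#'   spectra.
#' @param endmembers an [EndmemberSet-class] (spectra must be full rank).
#' @return a [FractionMap-class] with per-pixel fractions and residual RMS.
#' @seealso [generateMixedPixels()] for the forward model, [deltaNPV()]
#' @export
unmix <- function(reflectance, endmembers) {
  E <- endmemberSpectra(endmembers)
  v <- gridValues(reflectance)
  d <- dim(v)
  if (d[3] != nrow(E))
    stop("band count (", d[3], ") does not match the endmember spectra (",
         nrow(E), " bands)", call. = FALSE)
  if (qr(E)$rank < ncol(E))
    stop("endmember matrix is rank deficient", call. = FALSE)
  m <- ncol(E)
  R <- t(matrix(v, d[1] * d[2], d[3]))       # bands x pixels
  K <- rbind(cbind(crossprod(E), rep(1, m)), c(rep(1, m), 0))
  rhs <- rbind(t(E) %*% R, rep(1, ncol(R)))
  sol <- solve(K, rhs)                       # (m+1) x pixels
  f <- sol[seq_len(m), , drop = FALSE]
  resid <- R - E %*% f
  rms <- sqrt(colMeans(resid^2))
  nNeg <- sum(apply(f, 2, function(col) any(col < -1e-9)))
  if (nNeg > 0)
    message("unmix: ", nNeg, " pixel(s) have a negative fraction")
  new("FractionMap",
      fractions = array(t(f), c(d[1], d[2], m)),
      rms = matrix(rms, d[1], d[2]),
      endmemberNames = colnames(E),
      resolution = gridResolution(reflectance),
      origin = gridOrigin(reflectance), crs = gridCRS(reflectance))
}

#' Change in the non-photosynthetic vegetation fraction
#'
#' Per-pixel `f_NPV(post) - f_NPV(pre)`. Tree mortality exposes dead wood
#' to the sensor, so a disturbance raises NPV; the mean of this map is the
#' standard optical blowdown-detection signal.
#'
#' @param pre,post [FractionMap-class] objects on the same grid with an
#'   `NPV` endmember.
#' @return a [GridLayer-class] of the NPV fraction change.
#' @export
deltaNPV <- function(pre, post) {
  stopIfGeometryMismatch(pre, post, "fraction maps")
  iPre <- match("NPV", pre@endmemberNames)
  iPost <- match("NPV", post@endmemberNames)
  if (is.na(iPre) || is.na(iPost))
    stop("both fraction maps need an 'NPV' endmember", call. = FALSE)
  gridLayer(post@fractions[, , iPost] - pre@fractions[, , iPre],
            resolution = gridResolution(pre), origin = gridOrigin(pre),
            crs = gridCRS(pre))
}

#' One-sample t-test for positive NPV change
#'
#' Two-sided one-sample t-test of mean `dNPV = 0` over non-nodata pixels
#' (degrees of freedom `n - 1`). A significantly positive mean indicates
#' the disturbance is detectable in the optical record.
#'
#' @param dnpv a [GridLayer-class] from [deltaNPV()], or a numeric vector.
#' @return an object of class `htest` (see [stats::t.test()]).
#' @export
testPositiveDNPV <- function(dnpv) {
  x <- if (methods::is(dnpv, "GridLayer")) as.vector(gridValues(dnpv))
       else as.numeric(dnpv)
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 non-nodata pixels", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero variance in dNPV: t statistic undefined", call. = FALSE)
  stats::t.test(x, mu = 0)
}

#' Regress NPV change on carbon loss
#'
#' Ordinary least squares of per-cell `dNPV` on per-cell ACD loss. A low
#' `r2` here quantifies how weakly the optical change signal tracks the
#' true carbon loss.
#'
#' @param dnpv numeric vector or [GridLayer-class] of NPV change.
#' @param acdLoss numeric vector or [GridLayer-class] of ACD loss
#'   (Mg C ha^-1), paired with `dnpv` (same grid when rasters).
#' @return list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
regressDNPVOnACDLoss <- function(dnpv, acdLoss) {
  if (methods::is(dnpv, "GridLayer") && methods::is(acdLoss, "GridLayer"))
    stopIfGeometryMismatch(dnpv, acdLoss, "regression rasters")
  y <- if (methods::is(dnpv, "GridLayer")) as.vector(gridValues(dnpv))
       else as.numeric(dnpv)
  x <- if (methods::is(acdLoss, "GridLayer")) as.vector(gridValues(acdLoss))
       else as.numeric(acdLoss)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired cells", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant predictor: regression undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p = unname(s$coefficients[2, 4]),
       n = length(x))
}
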