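#' @include canopy-rasters.R
NULL

#' Fit the TCH-to-AGBD power allometry by Gaussian maximum likelihood
#'
#' Fits `AGBD = a * TCH^b` with additive normal residuals on the biomass
#' scale. The Gaussian likelihood is maximized through its profile form:
#' for fixed `(a, b)` the ML residual standard deviation is
#' `sqrt(SSE / n)`, so minimizing `n/2 * log(SSE/n)` over `(log a, b)` by
#' quasi-Newton (BFGS, started from the log-log least-squares line) yields
#' the joint ML estimate. This route remains exact as the residuals shrink
#' to zero, where a direct three-parameter optimization degenerates.
#'
#' @param plots data.frame with columns `tch_m` (> 0, not all equal) and
#'   `agbd_mg_ha` (>= 0); at least 3 rows.
#' @return an [AllometricFit-class] with `a`, `b`, the ML `sigma`, `r2`,
#'   RMSE as \% of mean AGBD, and the asymptotic covariance of `(log a, b)`
#'   used by [monteCarloACD()] when parameter uncertainty is requested.
#' @examples
#' plots <- generatePlots(allometrySimConfig(residualSd = 0))
#' fitAllometry(plots)
#' @export
fitAllometry <- function(plots) {
  if (!all(c("tch_m", "agbd_mg_ha") %in% names(plots)))
    stop("plots must have columns tch_m and agbd_mg_ha", call. = FALSE)
  tch <- plots$tch_m
  agbd <- plots$agbd_mg_ha
  n <- length(tch)
  if (n < 3L) stop("need at least 3 plots", call. = FALSE)
  if (any(tch <= 0)) stop("tch_m must be > 0", call. = FALSE)
  if (any(agbd < 0)) stop("agbd_mg_ha must be >= 0", call. = FALSE)
  if (length(unique(tch)) < 2L)
    stop("plots must span distinct TCH values", call. = FALSE)
  sst <- sum((agbd - mean(agbd))^2)
  if (sst <= 0)
    stop("degenerate AGBD variance: all plot values identical", call. = FALSE)

  sse <- function(p) sum((agbd - exp(p[1]) * tch^p[2])^2)
  # log-log least squares start (exact when residuals are zero)
  pos <- agbd > 0
  if (sum(pos) >= 2L) {
    ll <- stats::lm(log(agbd[pos]) ~ log(tch[pos]))
    start <- c(stats::coef(ll)[[1]], stats::coef(ll)[[2]])
  } else start <- c(log(max(mean(agbd), 1e-3)), 1)

  floorSSE <- 1e-20 * sst
  if (sse(start) > floorSSE) {
    obj <- function(p) n / 2 * log((sse(p) + floorSSE) / n)
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 1000))
    if (opt$convergence != 0)
      stop("allometry fit did not converge (optim code ", opt$convergence,
           "): ", opt$message, call. = FALSE)
    par <- opt$par
  } else par <- start
  a <- exp(par[1]); b <- par[2]
  finalSSE <- sse(par)
  sigma <- sqrt(finalSSE / n)
  # asymptotic covariance of (log a, b): sigma^2 (J'J)^-1 with the analytic
  # Jacobian of the mean function
  pred <- a * tch^b
  J <- cbind(pred, pred * log(tch))
  vc <- if (sigma > 0) sigma^2 * solve(crossprod(J)) else matrix(0, 2, 2)
  new("AllometricFit", a = a, b = b, sigma = sigma,
      r2 = 1 - finalSSE / sst,
      rmsePct = sqrt(finalSSE / n) / mean(agbd) * 100,
      n = as.integer(n), vcov = vc,
      plotData = as.data.frame(plots))
}

#' Predict AGBD from a TCH raster
#'
#' Applies `a * TCH^b` cell-wise; TCH of 0 maps to 0 and nodata propagates.
#'
#' @param fit an [AllometricFit-class].
#' @param tch a [GridLayer-class] (or [HeightRaster-class]) of TCH (m), or a
#'   numeric vector/matrix.
#' @return an object of the same kind as `tch` with AGBD in Mg ha^-1.
#' @export
predictAGBD <- function(fit, tch) {
  f <- function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("TCH must be >= 0", call. = FALSE)
    fit@a * v^fit@b
  }
  if (methods::is(tch, "GridLayer"))
    gridLayer(f(gridValues(tch)), resolution = gridResolution(tch),
              origin = gridOrigin(tch), crs = gridCRS(tch))
  else f(tch)
}

#' Convert AGBD to aboveground carbon density
#'
#' Element-wise multiplication by the carbon fraction of dry biomass
#' (default 0.47).
#'
#' @param agbd numeric vector/matrix or [GridLayer-class] of AGBD
#'   (Mg ha^-1, >= 0).
#' @param carbonFraction scalar in (0, 1].
#' @return same shape as `agbd`, in Mg C ha^-1.
#' @export
agbdToACD <- function(agbd, carbonFraction = 0.47) {
  if (carbonFraction <= 0 || carbonFraction > 1)
    stop("carbonFraction must be in (0, 1]", call. = FALSE)
  if (methods::is(agbd, "GridLayer")) {
    v <- gridValues(agbd)
    if (any(v < 0, na.rm = TRUE)) stop("AGBD must be >= 0", call. = FALSE)
    gridLayer(v * carbonFraction, resolution = gridResolution(agbd),
              origin = gridOrigin(agbd), crs = gridCRS(agbd))
  } else {
    if (any(agbd < 0, na.rm = TRUE)) stop("AGBD must be >= 0", call. = FALSE)
    agbd * carbonFraction
  }
}

#' Monte Carlo ACD map with 95\% uncertainty bounds
#'
#' Propagates allometric uncertainty into the carbon map by parametric
#' bootstrap: each of `nDraws` replicate AGBD maps is the model prediction
#' plus independent `N(0, sigma)` residual noise per cell, truncated at zero
#' to keep carbon physical, and converted to ACD. Per-cell and
#' landscape-mean 2.5/97.5 percentiles are reported.
#'
#' By default only the residual term is resampled. With
#' `perturbParams = TRUE` each draw additionally samples `(log a, b)` from
#' the asymptotic ML covariance; landscape-mean uncertainty is dominated by
#' parameter error rather than residual error (which averages out over
#' cells), so landscape-level inference should use this option.
#'
#' Two epochs mapped with the same `seed` share the same parameter draws
#' (paired draws), while `residualSeed` should differ between epochs so that
#' residual noise stays independent; [acdChange()] relies on this pairing.
#'
#' @param fit an [AllometricFit-class].
#' @param cellTch [GridLayer-class] of TCH on the analysis grid
#'   (conventionally 0.5-ha cells from [aggregateMean()]).
#' @param nDraws number of Monte Carlo draws (>= 2), default 1000.
#' @param seed RNG seed for parameter draws.
#' @param residualSeed RNG seed for residual draws (default `seed + 1`).
#' @param perturbParams also draw `(log a, b)` from the ML covariance.
#' @param carbonFraction carbon fraction of dry biomass.
#' @return an [AcdMap-class].
#' @export
monteCarloACD <- function(fit, cellTch, nDraws = 1000L, seed = 1L,
                          residualSeed = seed + 1L, perturbParams = FALSE,
                          carbonFraction = 0.47) {
  nDraws <- as.integer(nDraws)
  if (nDraws < 2L) stop("nDraws must be >= 2", call. = FALSE)
  tch <- gridValues(cellTch)
  nr <- nrow(tch); nc <- ncol(tch)
  valid <- !is.na(tch)
  if (!any(valid)) stop("cellTch has no data cells", call. = FALSE)
  central <- carbonFraction * fit@a * tch^fit@b

  pars <- withSeed(seed, {
    if (perturbParams && any(fit@vcov != 0)) {
      L <- chol(fit@vcov)
      z <- matrix(stats::rnorm(2L * nDraws), nDraws, 2L)
      sweep(z %*% L, 2L, c(log(fit@a), fit@b), "+")
    } else matrix(rep(c(log(fit@a), fit@b), each = nDraws), nDraws, 2L)
  })
  nCell <- sum(valid)
  eps <- withSeed(residualSeed,
                  matrix(stats::rnorm(nCell * nDraws, 0, fit@sigma),
                         nCell, nDraws))
  tv <- tch[valid]
  draws <- array(NA_real_, c(nr, nc, nDraws))
  landscape <- numeric(nDraws)
  flat <- matrix(NA_real_, nr * nc, nDraws)
  vidx <- which(valid)
  for (d in seq_len(nDraws)) {
    predD <- exp(pars[d, 1L]) * tv^pars[d, 2L]
    acdD <- carbonFraction * pmax(predD + eps[, d], 0)
    flat[vidx, d] <- acdD
    landscape[d] <- mean(acdD)
  }
  draws[] <- flat
  qs <- apply(flat[vidx, , drop = FALSE], 1L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  ciLow <- ciHigh <- matrix(NA_real_, nr, nc)
  ciLow[vidx] <- qs[1L, ]
  ciHigh[vidx] <- qs[2L, ]
  new("AcdMap", values = central, ciLow = ciLow, ciHigh = ciHigh,
      carbonFraction = carbonFraction, cellDraws = draws,
      landscapeDraws = landscape,
      landscapeCI = as.numeric(stats::quantile(landscape, c(0.025, 0.975))),
      settings = list(nDraws = nDraws, seed = seed,
                      residualSeed = residualSeed,
                      perturbParams = perturbParams,
                      a = fit@a, b = fit@b, sigma = fit@sigma),
      resolution = gridResolution(cellTch), origin = gridOrigin(cellTch),
      crs = gridCRS(cellTch))
}

#' ACD change between two epochs with Monte Carlo intervals
#'
#' Cell-wise and landscape-mean change (post minus pre) in absolute terms
#' and as a percentage of the pre-disturbance value. Uncertainty comes from
#' differencing paired Monte Carlo draws: both maps must have been built
#' from the same fit with the same number of draws, and should share the
#' parameter seed (so that parameter error cancels correctly in the paired
#' difference) while using distinct residual seeds.
#'
#' @param pre,post [AcdMap-class] objects on the same grid.
#' @return a list:
#' \describe{
#'   \item{cellChange}{[GridLayer-class] of absolute change (Mg C ha^-1).}
#'   \item{cellPctChange}{[GridLayer-class] of \% change relative to pre.}
#'   \item{landscape}{list with `meanPre`, `meanPost`, `change`, `pctChange`,
#'     `changeCI`, `pctChangeCI` (95\% Monte Carlo intervals).}
#' }
#' @export
acdChange <- function(pre, post) {
  stopIfGeometryMismatch(pre, post, "ACD maps")
  sPre <- pre@settings; sPost <- post@settings
  if (abs(sPre$a - sPost$a) > 1e-12 || abs(sPre$b - sPost$b) > 1e-12 ||
      abs(sPre$sigma - sPost$sigma) > 1e-12)
    stop("both epochs must use the same allometric fit", call. = FALSE)
  if (sPre$nDraws != sPost$nDraws)
    stop("both epochs must use the same number of draws", call. = FALSE)
  if (!identical(sPre$seed, sPost$seed) &&
      (isTRUE(sPre$perturbParams) || isTRUE(sPost$perturbParams)))
    warning("parameter seeds differ: draws are not paired on parameters",
            call. = FALSE)
  if (identical(sPre$residualSeed, sPost$residualSeed))
    warning("identical residual seeds: residual noise cancels in differences",
            call. = FALSE)
  vPre <- gridValues(pre); vPost <- gridValues(post)
  dAbs <- vPost - vPre
  dPct <- 100 * dAbs / ifelse(vPre == 0, NA, vPre)
  preMeanDraws <- pre@landscapeDraws
  postMeanDraws <- post@landscapeDraws
  chDraws <- postMeanDraws - preMeanDraws
  pctDraws <- 100 * chDraws / preMeanDraws
  valid <- !is.na(vPre) & !is.na(vPost)
  meanPre <- mean(vPre[valid]); meanPost <- mean(vPost[valid])
  list(
    cellChange = gridLayer(dAbs, resolution = gridResolution(pre),
                           origin = gridOrigin(pre), crs = gridCRS(pre)),
    cellPctChange = gridLayer(dPct, resolution = gridResolution(pre),
                              origin = gridOrigin(pre), crs = gridCRS(pre)),
    landscape = list(
      meanPre = meanPre, meanPost = meanPost,
      change = meanPost - meanPre,
      pctChange = 100 * (meanPost - meanPre) / meanPre,
      changeCI = as.numeric(stats::quantile(chDraws, c(0.025, 0.975))),
      pctChangeCI = as.numeric(stats::quantile(pctDraws, c(0.025, 0.975)))))
}
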