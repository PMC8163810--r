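#' @include acd-model.R gap-analysis.R height-transitions.R disturbance-detection.R recovery.R synthetic-data.R
NULL

#' Validate study-area bookkeeping
#'
#' Checks that the forest-type breakdown of a study area adds up: the
#' old-growth and secondary areas must sum to the declared total. Used to
#' validate pipeline configurations before any computation.
#'
#' @param oldGrowthHa old-growth area (ha).
#' @param secondaryHa secondary-forest area (ha).
#' @param totalHa declared total (ha); when given, a mismatch beyond 1e-9
#'   ha is an error.
#' @return the total area (ha).
#' @export
studyAreaHa <- function(oldGrowthHa, secondaryHa, totalHa = NULL) {
  if (oldGrowthHa < 0 || secondaryHa < 0)
    stop("areas must be >= 0", call. = FALSE)
  total <- oldGrowthHa + secondaryHa
  if (!is.null(totalHa) && abs(total - totalHa) > 1e-9)
    stop(sprintf("area bookkeeping mismatch: %.3f + %.3f = %.3f ha != declared %.3f ha",
                 oldGrowthHa, secondaryHa, total, totalHa), call. = FALSE)
  total
}

## ---------------------------------------------------------------------------
## Flat key-value config (DCF dialect)
## ---------------------------------------------------------------------------

## Config files use the DCF dialect ("Key: value", one per line) read by
## base R's read.dcf. Numeric-looking values are converted; lists are
## comma-separated.

#' Read a pipeline configuration file
#'
#' @param file a DCF-format (`Key: value`) configuration file, one key per
#'   line; comma-separated values become numeric vectors where possible.
#' @return a named list.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("no such config file: ", file, call. = FALSE)
  raw <- read.dcf(file)
  cfg <- as.list(raw[1, ])
  lapply(cfg, function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(nums))) nums else if (length(parts) > 1) parts else v
  })
}

#' Write a pipeline configuration file
#'
#' @param config named list of scalar or vector values.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePipelineConfig <- function(config, file) {
  flat <- vapply(config, function(v) paste(format(v, trim = TRUE),
                                           collapse = ", "), character(1))
  write.dcf(matrix(flat, 1, dimnames = list(NULL, names(config))), file)
  invisible(file)
}

## ---------------------------------------------------------------------------
## Demo workspace
## ---------------------------------------------------------------------------

## internal: simulate lidar-style returns over a canopy surface + terrain.
## Uniform scatter; first returns sample the canopy surface (bilinear),
## later returns fall mid-canopy. Scan angles uniform within +/- 20 deg.
simulateReturns <- function(chm, dtm, densityPtsM2, firstFraction = 0.85,
                            zNoiseSd = 0.1, biasM = 0, seed = 1L) {
  ext <- gridExtent(chm)
  area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  n <- round(densityPtsM2 * area)
  withSeed(seed, {
    x <- stats::runif(n, ext[1], ext[2] - 1e-9)
    y <- stats::runif(n, ext[3], ext[4] - 1e-9)
    canopy <- bilinearSample(chm, x, y)
    ground <- bilinearSample(dtm, x, y)
    rn <- ifelse(stats::runif(n) < firstFraction, 1L,
                 sample(2:3, n, replace = TRUE))
    depth <- ifelse(rn == 1L, 0, stats::runif(n, 0.3, 0.7) * canopy)
    z <- ground + pmax(canopy - depth, 0) +
      stats::rnorm(n, 0, zNoiseSd) + biasM
    data.frame(x = x, y = y, z = z, return_number = rn,
               scan_angle = stats::runif(n, -20, 20))
  })
}

## internal: synthetic smooth terrain on the CHM grid
syntheticDTM <- function(chm, baseElevM = 50, reliefM = 8, seed = 99L) {
  v <- gridValues(chm)
  nr <- nrow(v); nc <- ncol(v)
  withSeed(seed, {
    noise <- boxSmooth(matrix(stats::rnorm(nr * nc), nr, nc), 31L)
    noise <- (noise - mean(noise)) / stats::sd(noise)
    heightRaster(baseElevM + reliefM * (noise - min(noise)) /
                   (max(noise) - min(noise)),
                 resolution = gridResolution(chm), origin = gridOrigin(chm))
  })
}

## internal: annual plot ACD series with episodic large losses followed by
## an elevated-gain phase, used to calibrate the recovery fast phase
simulatePlotSeries <- function(nYears = 30L, acd0 = 95, longTermGain = 0.49,
                               eventYears = c(5L, 12L, 18L, 24L),
                               eventLoss = 14,
                               elevatedGains = c(2.0, 1.6, 1.3, 1.0, 0.8),
                               noiseSd = 0.15, seed = 1L) {
  withSeed(seed, {
    acd <- numeric(nYears)
    acd[1] <- acd0
    sinceEvent <- Inf
    for (t in 2:nYears) {
      if ((t - 1L) %in% eventYears) {
        acd[t] <- acd[t - 1] - eventLoss + stats::rnorm(1, 0, noiseSd)
        sinceEvent <- 0
      } else {
        sinceEvent <- sinceEvent + 1
        gain <- if (sinceEvent <= length(elevatedGains))
          elevatedGains[sinceEvent] else longTermGain
        acd[t] <- acd[t - 1] + gain + stats::rnorm(1, 0, noiseSd)
      }
    }
    acd
  })
}

#' Build a ready-to-run synthetic demo workspace
#'
#' Generates a paired pre/post landscape (a synthetic canopy disturbed by
#' [applyBlowdown()]), lidar-style point tables for both epochs, a terrain
#' model, allometry calibration plots, an annual plot ACD series, endmember
#' spectra and pre/post mixed reflectance, writes everything as plain-text
#' files, and emits a configuration file that [runPipeline()] accepts
#' directly.
#'
#' The pre epoch emulates an aircraft survey (no scan-angle filter, no
#' subsampling, a +0.7 m vertical bias to be corrected); the post epoch
#' emulates a drone survey (scan angle within 15 degrees, subsampled to a
#' homogeneous density).
#'
#' @param dir workspace directory (created if missing).
#' @param seed master RNG seed; every stage seed derives from it.
#' @param extentM landscape size (m).
#' @param severity fraction of canopy volume removed by the blowdown.
#' @param densityPtsM2 raw point density of the simulated surveys.
#' @return the path of the written config file, invisibly.
#' @export
makeDemo <- function(dir, seed = 1L, extentM = 210, severity = 0.2,
                     densityPtsM2 = 1.8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cfgForest <- syntheticForestConfig(extentM = extentM, seed = seed)
  chmPre <- generateCHM(cfgForest)
  dtm <- syntheticDTM(chmPre, seed = seed + 10L)
  blow <- applyBlowdown(chmPre, severity = severity, seed = seed + 20L)

  ptsPre <- simulateReturns(chmPre, dtm, densityPtsM2, biasM = 0.7,
                            seed = seed + 30L)
  ptsPost <- simulateReturns(blow$chm, dtm, densityPtsM2, seed = seed + 40L)
  writePointCsv(ptsPre, file.path(dir, "points_pre.csv"))
  writePointCsv(ptsPost, file.path(dir, "points_post.csv"))
  writeAsciiGrid(dtm, file.path(dir, "dtm.asc"))
  writeAsciiGrid(blow$trueChange, file.path(dir, "true_change.asc"))
  writeAsciiGrid(chmPre, file.path(dir, "chm_true_pre.asc"))

  plots <- generatePlots(allometrySimConfig(seed = seed + 50L))
  utils::write.csv(plots, file.path(dir, "plots.csv"), row.names = FALSE,
                   quote = FALSE)
  series <- simulatePlotSeries(seed = seed + 60L)
  utils::write.csv(data.frame(year = seq_along(series), acd_mg_c_ha = series),
                   file.path(dir, "plot_series.csv"), row.names = FALSE,
                   quote = FALSE)

  em <- endmemberSet()
  writeEndmemberCsv(em, file.path(dir, "endmembers.csv"))
  refl <- simulateReflectancePair(chmPre, blow$trueChange, em,
                                  seed = seed + 70L)
  writeBandRaster(refl$pre, file.path(dir, "reflectance_pre"))
  writeBandRaster(refl$post, file.path(dir, "reflectance_post"))

  cfg <- list(
    points_pre = file.path(dir, "points_pre.csv"),
    points_post = file.path(dir, "points_post.csv"),
    dtm = file.path(dir, "dtm.asc"),
    plots_csv = file.path(dir, "plots.csv"),
    plot_series_csv = file.path(dir, "plot_series.csv"),
    endmembers_csv = file.path(dir, "endmembers.csv"),
    reflectance_pre_prefix = file.path(dir, "reflectance_pre"),
    reflectance_post_prefix = file.path(dir, "reflectance_post"),
    reflectance_bands = paste(em@bands, collapse = ","),
    out_dir = file.path(dir, "out"),
    seed = seed,
    pre_bias_m = 0.7,
    pre_filter_scan_angle = 0,
    pre_subsample = 0,
    post_bias_m = 0,
    post_filter_scan_angle = 1,
    post_subsample = 1,
    max_abs_scan_angle_deg = 15,
    target_density_pts_m2 = 1.0,
    chm_resolution_m = 1.25,
    tch_resolution_m = 5,
    acd_cell_factor = 14,
    carbon_fraction = 0.47,
    mc_draws = 1000,
    mc_perturb_params = 1,
    gap_thresholds = paste(seq(2, 20, 2), collapse = ","),
    lambda_threshold_m = 8,
    mcmc_chain = 100000,
    mcmc_burnin = 5000,
    mcmc_thin = 25,
    dirichlet_draws = 10000,
    long_term_gain = 0.49,
    baseline_adjust_gain = 0.74,
    baseline_adjust_years = 9,
    old_growth_ha = 33.0,
    secondary_ha = 70.5,
    study_area_ha = 103.5)
  cfgPath <- file.path(dir, "config.dcf")
  writePipelineConfig(cfg, cfgPath)
  invisible(cfgPath)
}

## internal: pre/post mixed reflectance on a 30 m grid; NPV rises inside
## disturbed cells in proportion to the local fraction of canopy removed
simulateReflectancePair <- function(chmPre, trueChange, em, noiseSd = 0.004,
                                    seed = 1L) {
  lossFrac <- resampleAreaWeighted(
    gridLayer(pmin(pmax(-gridValues(trueChange), 0) /
                     pmax(gridValues(chmPre), 1), 1),
              resolution = gridResolution(chmPre),
              origin = gridOrigin(chmPre)),
    resolutionM = 30)
  lf <- gridValues(lossFrac)
  nr <- nrow(lf); nc <- ncol(lf)
  withSeed(seed, {
    npvPre <- matrix(stats::runif(nr * nc, 0.04, 0.10), nr, nc)
    shade <- matrix(stats::runif(nr * nc, 0.10, 0.20), nr, nc)
    mkFrac <- function(npv) {
      f <- array(0, c(nr, nc, 3))
      f[, , 2] <- npv
      f[, , 3] <- shade
      f[, , 1] <- 1 - npv - shade
      f
    }
    npvPost <- pmin(npvPre + 0.30 * lf, 0.95 - shade)
    list(pre = generateMixedPixels(mkFrac(npvPre), em, noiseSd = noiseSd,
                                   seed = seed + 1L, resolutionM = 30),
         post = generateMixedPixels(mkFrac(npvPost), em, noiseSd = noiseSd,
                                    seed = seed + 2L, resolutionM = 30))
  })
}

## ---------------------------------------------------------------------------
## Pipeline
## ---------------------------------------------------------------------------

## internal: one epoch of point processing -> list(chm 1.25 m, tch 5 m)
processEpoch <- function(points, dtm, cfg, filterAngle, subsample, biasM,
                         seed) {
  if (filterAngle)
    points <- filterReturns(points, cfg$max_abs_scan_angle_deg)
  else
    points <- points[points$return_number == 1, , drop = FALSE]
  if (biasM != 0) points <- applyVerticalBias(points, biasM)
  points <- heightAboveGround(points, dtm)
  if (subsample) {
    ext <- gridExtent(dtm)
    points <- subsampleDensity(points, cfg$target_density_pts_m2,
                               (ext[2] - ext[1]) * (ext[4] - ext[3]),
                               seed = seed)
  }
  ext <- gridExtent(dtm)
  list(chm = rasterizeTIN(points, resolutionM = cfg$chm_resolution_m,
                          extent = ext),
       tch = rasterizeMean(points, resolutionM = cfg$tch_resolution_m,
                           extent = ext),
       nPoints = nrow(points))
}

#' Run the full blowdown analysis pipeline
#'
#' Executes, in order: point filtering and rasterization for both epochs,
#' allometry fitting and Monte Carlo ACD mapping with landscape change,
#' gap labeling and power-law exponent estimation at a ladder of height
#' thresholds, the height-transition steady-state projection with its
#' Dirichlet posterior, spectral unmixing and NPV change testing, and
#' recovery-time bookkeeping. Per-stage outputs (CSV/ASCII-grid) and a
#' machine-readable JSON summary are written under the configured output
#' directory; all inputs, seeds and parameter values are logged into the
#' summary so a run is auditable.
#'
#' All referenced input files are checked before any computation; a missing
#' file is an immediate error naming the path. A stage failure aborts the
#' run naming the stage.
#'
#' @param config path to a DCF config file (see [makeDemo()]) or an
#'   equivalent named list.
#' @return the summary list, invisibly; also written as `summary.json`.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  fileKeys <- c("points_pre", "points_post", "dtm", "plots_csv",
                "plot_series_csv", "endmembers_csv")
  for (k in fileKeys)
    if (!file.exists(cfg[[k]]))
      stop("missing input file for '", k, "': ", cfg[[k]], call. = FALSE)
  bands <- cfg$reflectance_bands
  if (length(bands) == 1L) bands <- trimws(strsplit(bands, ",")[[1]])
  for (pfx in c(cfg$reflectance_pre_prefix, cfg$reflectance_post_prefix))
    for (b in bands)
      if (!file.exists(paste0(pfx, "_", b, ".asc")))
        stop("missing reflectance band file: ", paste0(pfx, "_", b, ".asc"),
             call. = FALSE)
  studyAreaHa(cfg$old_growth_ha, cfg$secondary_ha, cfg$study_area_ha)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- canopy rasters -----------------------------------------------------
  ras <- stage("canopy_rasters", {
    dtm <- readAsciiGrid(cfg$dtm, class = "HeightRaster")
    pre <- processEpoch(readPointCsv(cfg$points_pre), dtm, cfg,
                        filterAngle = cfg$pre_filter_scan_angle > 0,
                        subsample = cfg$pre_subsample > 0,
                        biasM = cfg$pre_bias_m, seed = seed + 1L)
    post <- processEpoch(readPointCsv(cfg$points_post), dtm, cfg,
                         filterAngle = cfg$post_filter_scan_angle > 0,
                         subsample = cfg$post_subsample > 0,
                         biasM = cfg$post_bias_m, seed = seed + 2L)
    writeAsciiGrid(pre$chm, file.path(outDir, "chm_pre.asc"))
    writeAsciiGrid(post$chm, file.path(outDir, "chm_post.asc"))
    writeAsciiGrid(heightChange(pre$tch, post$tch),
                   file.path(outDir, "tch_change.asc"))
    list(pre = pre, post = post)
  })

  ## --- ACD ----------------------------------------------------------------
  acd <- stage("acd_model", {
    plots <- utils::read.csv(cfg$plots_csv)
    fit <- fitAllometry(plots)
    cellPre <- aggregateMean(ras$pre$tch, cfg$acd_cell_factor)
    cellPost <- aggregateMean(ras$post$tch, cfg$acd_cell_factor)
    mapPre <- monteCarloACD(fit, cellPre, nDraws = cfg$mc_draws,
                            seed = seed + 3L, residualSeed = seed + 4L,
                            perturbParams = cfg$mc_perturb_params > 0,
                            carbonFraction = cfg$carbon_fraction)
    mapPost <- monteCarloACD(fit, cellPost, nDraws = cfg$mc_draws,
                             seed = seed + 3L, residualSeed = seed + 5L,
                             perturbParams = cfg$mc_perturb_params > 0,
                             carbonFraction = cfg$carbon_fraction)
    change <- acdChange(mapPre, mapPost)
    writeAsciiGrid(change$cellChange, file.path(outDir, "acd_change.asc"))
    utils::write.csv(
      data.frame(a = fit@a, b = fit@b, sigma = fit@sigma, r2 = fit@r2,
                 rmse_pct = fit@rmsePct, n = fit@n),
      file.path(outDir, "allometry_fit.csv"), row.names = FALSE)
    list(fit = fit, mapPre = mapPre, mapPost = mapPost, change = change)
  })

  ## --- gaps ---------------------------------------------------------------
  gaps <- stage("gap_analysis", {
    th <- cfg$gap_thresholds
    areaPre <- gapAreaByThreshold(ras$pre$chm, th)
    areaPost <- gapAreaByThreshold(ras$post$chm, th)
    utils::write.csv(cbind(epoch = "pre", areaPre),
                     file.path(outDir, "gap_area_pre.csv"), row.names = FALSE)
    utils::write.csv(cbind(epoch = "post", areaPost),
                     file.path(outDir, "gap_area_post.csv"), row.names = FALSE)
    lamTh <- cfg$lambda_threshold_m
    sizesPre <- gapSizes(labelGaps(ras$pre$chm, lamTh))
    sizesPost <- gapSizes(labelGaps(ras$post$chm, lamTh))
    postPre <- estimateLambda(sizesPre, nTotal = cfg$mcmc_chain,
                              nBurnin = cfg$mcmc_burnin, thin = cfg$mcmc_thin,
                              seed = seed + 6L)
    postPost <- estimateLambda(sizesPost, nTotal = cfg$mcmc_chain,
                               nBurnin = cfg$mcmc_burnin, thin = cfg$mcmc_thin,
                               seed = seed + 7L)
    cmp <- compareLambda(postPre, postPost)
    utils::write.csv(
      data.frame(epoch = c("pre", "post"), threshold_m = lamTh,
                 lambda_median = c(lambdaMedian(postPre),
                                   lambdaMedian(postPost)),
                 cri_low = c(credibleInterval(postPre)[1],
                             credibleInterval(postPost)[1]),
                 cri_high = c(credibleInterval(postPre)[2],
                              credibleInterval(postPost)[2]),
                 n_retained = c(length(posteriorChain(postPre)),
                                length(posteriorChain(postPost)))),
      file.path(outDir, "lambda_posteriors.csv"), row.names = FALSE)
    list(areaPre = areaPre, areaPost = areaPost, postPre = postPre,
         postPost = postPost, cmp = cmp,
         nGapsPre = length(sizesPre), nGapsPost = length(sizesPost))
  })

  ## --- height transitions -------------------------------------------------
  trans <- stage("height_transitions", {
    model <- buildTransitionMatrix(ras$pre$tch, ras$post$tch)
    ss <- steadyStatePosterior(model, nDraws = cfg$dirichlet_draws,
                               seed = seed + 8L)
    obs <- heightDistribution(ras$pre$tch, model@nClasses, model@classWidth)
    cmp <- compareDistributions(obs, ss)
    utils::write.csv(
      data.frame(class = seq_len(model@nClasses),
                 low_edge_m = model@edges[-length(model@edges)],
                 prob = stationaryDistribution(ss),
                 cri_low = ss@envLow, cri_high = ss@envHigh),
      file.path(outDir, "steady_state.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(transitionCounts(model)),
                     file.path(outDir, "transition_counts.csv"),
                     row.names = FALSE)
    list(model = model, ss = ss, cmp = cmp)
  })

  ## --- optical detection --------------------------------------------------
  det <- stage("disturbance_detection", {
    em <- readEndmemberCsv(cfg$endmembers_csv)
    reflPre <- readBandRaster(cfg$reflectance_pre_prefix, bands)
    reflPost <- readBandRaster(cfg$reflectance_post_prefix, bands)
    fPre <- unmix(reflPre, em)
    fPost <- unmix(reflPost, em)
    dnpv <- deltaNPV(fPre, fPost)
    tt <- testPositiveDNPV(dnpv)
    acdLossFine <- gridLayer(-gridValues(acd$change$cellChange),
                             resolution = gridResolution(acd$change$cellChange),
                             origin = gridOrigin(acd$change$cellChange))
    acdLoss30 <- resampleAreaWeighted(acdLossFine,
                                      gridResolution(dnpv),
                                      gridExtent(dnpv))
    reg <- regressDNPVOnACDLoss(dnpv, acdLoss30)
    writeAsciiGrid(dnpv, file.path(outDir, "dnpv.asc"))
    list(tt = tt, reg = reg,
         meanDnpv = mean(gridValues(dnpv), na.rm = TRUE),
         maxDnpv = max(gridValues(dnpv), na.rm = TRUE))
  })

  ## --- recovery -----------------------------------------------------------
  rec <- stage("recovery", {
    series <- utils::read.csv(cfg$plot_series_csv)$acd_mg_c_ha
    elevated <- estimateElevatedGains(series)
    loss <- max(-acd$change$landscape$change, 0)
    sc <- recoveryScenario(loss, longTermGain = cfg$long_term_gain,
                           elevatedGains = elevated,
                           baselineAdjustGain = cfg$baseline_adjust_gain,
                           baselineAdjustYears = cfg$baseline_adjust_years)
    scAdj <- adjustBaseline(sc)
    list(scenario = sc,
         longTerm = recoveryTimeLongTerm(sc),
         twoPhase = recoveryTimeTwoPhase(sc),
         longTermAdj = recoveryTimeLongTerm(scAdj),
         twoPhaseAdj = recoveryTimeTwoPhase(scAdj),
         elevatedGains = elevated)
  })

  summary <- list(
    parameters = cfg[order(names(cfg))],
    canopy_rasters = list(n_points_pre = ras$pre$nPoints,
                          n_points_post = ras$post$nPoints),
    allometry = list(a = acd$fit@a, b = acd$fit@b, sigma = acd$fit@sigma,
                     r2 = acd$fit@r2, rmse_pct = acd$fit@rmsePct),
    acd = list(mean_pre = acd$change$landscape$meanPre,
               mean_post = acd$change$landscape$meanPost,
               change = acd$change$landscape$change,
               pct_change = acd$change$landscape$pctChange,
               change_ci = acd$change$landscape$changeCI,
               pct_change_ci = acd$change$landscape$pctChangeCI),
    gaps = list(n_gaps_pre = gaps$nGapsPre, n_gaps_post = gaps$nGapsPost,
                lambda_pre = lambdaMedian(gaps$postPre),
                lambda_post = lambdaMedian(gaps$postPost),
                lambda_delta = gaps$cmp$deltaMedian,
                lambda_significant = gaps$cmp$significant),
    transitions = list(n_classes = trans$model@nClasses,
                       equilibrium_mean_m = meanCanopyHeight(trans$ss),
                       equilibrium_mean_ci = credibleInterval(trans$ss),
                       observed_pre_mean_m = trans$cmp$meanObserved,
                       tv_distance = trans$cmp$tvDistance,
                       departure = trans$cmp$departure),
    detection = list(t = unname(det$tt$statistic), df = unname(det$tt$parameter),
                     p = det$tt$p.value, mean_dnpv = det$meanDnpv,
                     max_dnpv = det$maxDnpv, r2 = det$reg$r2),
    recovery = list(acd_loss = rec$scenario@acdLoss,
                    elevated_gains = rec$elevatedGains,
                    years_long_term = rec$longTerm$years,
                    years_two_phase = rec$twoPhase$years,
                    years_long_term_adjusted = rec$longTermAdj$years,
                    years_two_phase_adjusted = rec$twoPhaseAdj$years))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
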