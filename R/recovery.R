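#' @include AllClasses.R
NULL

#' Construct a carbon recovery scenario
#'
#' Bookkeeping inputs for estimating how long forest regrowth needs to
#' replace the carbon lost to a disturbance. The long-term annual gain
#' (default 0.49 Mg C ha^-1 yr^-1, an old-growth multi-decade trend) gives
#' an upper-bound recovery time since regrowth directly after disturbance
#' is faster than the long-term trend; prepending a fast phase of elevated
#' annual gains (observed in the years following large local carbon losses)
#' gives a lower bound since not all of the landscape was disturbed. The
#' baseline adjustment extrapolates pre-event carbon accumulation (default
#' 0.74 Mg C ha^-1 yr^-1 over 9 years) onto the reference map, raising the
#' effective loss.
#'
#' @param acdLoss mean landscape ACD loss (Mg C ha^-1, >= 0).
#' @param longTermGain long-term annual ACD gain (Mg C ha^-1 yr^-1).
#' @param elevatedGains per-year gains of the initial fast phase
#'   (Mg C ha^-1 yr^-1); length = phase duration (default none).
#' @param baselineAdjustGain annual gain used by [adjustBaseline()].
#' @param baselineAdjustYears years between reference map and the event.
#' @return a [RecoveryScenario-class].
#' @export
recoveryScenario <- function(acdLoss, longTermGain = 0.49,
                             elevatedGains = numeric(0),
                             baselineAdjustGain = 0.74,
                             baselineAdjustYears = 9) {
  new("RecoveryScenario", acdLoss = acdLoss, longTermGain = longTermGain,
      elevatedGains = as.numeric(elevatedGains),
      baselineAdjustGain = baselineAdjustGain,
      baselineAdjustYears = baselineAdjustYears)
}

## internal: whole-year count from a continuous recovery time.
## Floor of the continuous time (a partly-completed final year does not
## count), except that any positive loss takes at least one year —
## regrowth is an annual bookkeeping increment, not a continuous flow.
wholeYears <- function(tCont, loss, rounding) {
  if (loss <= 0) return(0L)
  y <- if (rounding == "ceiling") ceiling(tCont - 1e-9) else floor(tCont + 1e-9)
  as.integer(max(1L, y))
}

#' Recovery time under the long-term growth trend
#'
#' Years needed for the long-term annual gain to accumulate to the lost
#' ACD. The default rounding is the integer part of the ratio (35 years
#' for a 17.4 Mg C ha^-1 loss at 0.49 Mg C ha^-1 yr^-1); `"ceiling"` counts
#' the final partial year as a full year.
#'
#' @param scenario a [RecoveryScenario-class] with `longTermGain > 0`.
#' @param rounding `"floor"` (default) or `"ceiling"`.
#' @return list with `years` (integer) and `ratio` (unrounded years).
#' @export
recoveryTimeLongTerm <- function(scenario, rounding = c("floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (scenario@longTermGain <= 0)
    stop("long-term gain must be > 0: no recovery otherwise", call. = FALSE)
  ratio <- scenario@acdLoss / scenario@longTermGain
  list(years = wholeYears(ratio, scenario@acdLoss, rounding), ratio = ratio)
}

#' Recovery time with an initial fast phase
#'
#' Accumulates the elevated annual gains year by year, then the long-term
#' gain, until the cumulative regrowth reaches the lost ACD. With no
#' elevated phase this reduces exactly to [recoveryTimeLongTerm()].
#'
#' @param scenario a [RecoveryScenario-class].
#' @param rounding `"floor"` (default) or `"ceiling"`.
#' @return list with `years` (integer), `ratio` (continuous-time years) and
#'   `elevatedYears` actually used.
#' @export
recoveryTimeTwoPhase <- function(scenario, rounding = c("floor", "ceiling")) {
  rounding <- match.arg(rounding)
  loss <- scenario@acdLoss
  gains <- scenario@elevatedGains
  if (scenario@longTermGain <= 0 && loss > sum(gains))
    stop("long-term gain must be > 0: no recovery otherwise", call. = FALSE)
  cumElev <- cumsum(gains)
  if (loss <= 0) {
    tCont <- 0
  } else if (length(gains) && loss <= cumElev[length(gains)]) {
    full <- sum(cumElev < loss)
    remainder <- loss - if (full > 0) cumElev[full] else 0
    tCont <- full + remainder / gains[full + 1L]
  } else {
    remainder <- loss - if (length(gains)) cumElev[length(gains)] else 0
    tCont <- length(gains) + remainder / scenario@longTermGain
  }
  list(years = wholeYears(tCont, loss, rounding), ratio = tCont,
       elevatedYears = length(gains))
}

#' Extrapolate the pre-event carbon baseline
#'
#' Raises the scenario's ACD loss by `baselineAdjustGain *
#' baselineAdjustYears`, accounting for carbon accumulated between the
#' reference survey and the disturbance (the reference map understates the
#' immediately pre-event stock). Additive: adjusting twice over split
#' periods equals one adjustment over their sum.
#'
#' @param scenario a [RecoveryScenario-class].
#' @param years override for `baselineAdjustYears` (optional).
#' @return a new [RecoveryScenario-class] with the enlarged loss.
#' @export
adjustBaseline <- function(scenario, years = NULL) {
  yrs <- if (is.null(years)) scenario@baselineAdjustYears else years
  recoveryScenario(
    acdLoss = scenario@acdLoss + scenario@baselineAdjustGain * yrs,
    longTermGain = scenario@longTermGain,
    elevatedGains = scenario@elevatedGains,
    baselineAdjustGain = scenario@baselineAdjustGain,
    baselineAdjustYears = scenario@baselineAdjustYears)
}

#' Estimate elevated post-disturbance gains from a plot ACD series
#'
#' Identifies disturbance years in an annual plot ACD record as years whose
#' ACD loss exceeds `lossThreshold` (Mg C ha^-1), then averages, across
#' events, the annual ACD gain in each of the `phaseYears` years following
#' an event. The result feeds `elevatedGains` in [recoveryScenario()].
#'
#' @param acdSeries numeric vector of annual ACD values (Mg C ha^-1),
#'   ordered in time.
#' @param lossThreshold annual loss defining a disturbance event (default
#'   11.5 Mg C ha^-1).
#' @param phaseYears number of post-event years to average (default 5).
#' @return numeric vector of length `phaseYears` (mean gain per post-event
#'   year, NA-dropped); empty with a warning when no event is found.
#' @export
estimateElevatedGains <- function(acdSeries, lossThreshold = 11.5,
                                  phaseYears = 5L) {
  d <- diff(acdSeries)
  events <- which(d < -lossThreshold)
  if (!length(events)) {
    warning("no annual loss exceeds the threshold; no elevated phase",
            call. = FALSE)
    return(numeric(0))
  }
  gains <- sapply(seq_len(phaseYears), function(k) {
    idx <- events + k
    mean(d[idx[idx <= length(d)]], na.rm = TRUE)
  })
  pmax(gains, 0)
}
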