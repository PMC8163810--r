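#' @include canopy-rasters.R
NULL

#' Label canopy gaps at a height threshold
#'
#' A gap is a maximal 8-connected component (diagonal neighbours included)
#' of pixels with canopy height at or below `thresholdM`; the classic field
#' definition uses 2 m, generalized here to an arbitrary threshold ladder.
#' Nodata pixels are never gap pixels. Components touching the raster edge
#' are included (excluding them would bias against large gaps in a bounded
#' study window); set `dropEdgeGaps = TRUE` to exclude them.
#'
#' @param chm a [HeightRaster-class]; 1.25 m is the conventional resolution
#'   (other resolutions are accepted with a message).
#' @param thresholdM height cutoff (m).
#' @param dropEdgeGaps drop components touching the raster edge.
#' @return a [GapLabelMap-class]; labels are 1..n in order of first
#'   (row-major) appearance.
#' @seealso [gapSizes()], [gapAreaByThreshold()]
#' @export
labelGaps <- function(chm, thresholdM, dropEdgeGaps = FALSE) {
  if (abs(gridResolution(chm) - 1.25) > 1e-9)
    message(sprintf("labelGaps: non-standard CHM resolution %g m",
                    gridResolution(chm)))
  v <- gridValues(chm)
  nr <- nrow(v); nc <- ncol(v)
  mask <- !is.na(v) & v <= thresholdM
  labels <- matrix(0L, nr, nc)
  if (any(mask)) {
    cellId <- which(mask)                  # column-major linear ids
    rank <- integer(nr * nc)               # 1..n over gap pixels
    rank[cellId] <- seq_along(cellId)
    row <- ((cellId - 1L) %% nr) + 1L
    col <- ((cellId - 1L) %/% nr) + 1L
    edges <- NULL
    for (sh in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
      nrow2 <- row + sh[1L]; ncol2 <- col + sh[2L]
      ok <- nrow2 >= 1L & nrow2 <= nr & ncol2 >= 1L & ncol2 <= nc
      nid <- (ncol2[ok] - 1L) * nr + nrow2[ok]
      both <- mask[nid]
      edges <- rbind(edges, cbind(rank[cellId[ok][both]], rank[nid[both]]))
    }
    g <- igraph::graph_from_data_frame(
      d = if (is.null(edges)) data.frame(from = integer(0), to = integer(0))
          else data.frame(from = edges[, 1L], to = edges[, 2L]),
      directed = FALSE,
      vertices = data.frame(name = seq_along(cellId)))
    memb <- igraph::components(g)$membership[as.character(seq_along(cellId))]
    # relabel deterministically by first row-major appearance
    ord <- order(row, col)
    first <- !duplicated(memb[ord])
    relab <- integer(max(memb))
    relab[memb[ord][first]] <- seq_len(sum(first))
    labels[cellId] <- relab[memb]
    if (dropEdgeGaps) {
      edgeLabs <- unique(c(labels[1, ], labels[nr, ], labels[, 1],
                           labels[, nc]))
      edgeLabs <- edgeLabs[edgeLabs > 0L]
      if (length(edgeLabs)) {
        labels[labels %in% edgeLabs] <- 0L
        keep <- sort(unique(labels[labels > 0L]))
        remap <- integer(max(keep, 0L))
        remap[keep] <- seq_along(keep)
        labels[labels > 0L] <- remap[labels[labels > 0L]]
      }
    }
  }
  new("GapLabelMap", labels = labels, threshold = thresholdM,
      connectivity = 8L, resolution = gridResolution(chm),
      origin = gridOrigin(chm), crs = gridCRS(chm))
}

#' Gap sizes in pixels
#'
#' @param labelMap a [GapLabelMap-class].
#' @return integer vector of pixel counts, one per gap (possibly empty). The
#'   multiset of sizes, not the label ids, is the meaningful contract.
#' @export
gapSizes <- function(labelMap) {
  l <- labelMap@labels
  if (!any(l > 0L)) return(integer(0))
  as.integer(tabulate(l[l > 0L]))
}

#' Gap area statistics over a ladder of height thresholds
#'
#' For each threshold: the number of gaps, total gap area, and gap area as a
#' percentage of the non-nodata study area. Gap area is non-decreasing in
#' the threshold since the gap pixel sets are nested.
#'
#' @param chm a [HeightRaster-class].
#' @param thresholds ascending height thresholds (m); the conventional
#'   ladder is 2 to 20 m in 2 m steps.
#' @return data.frame with columns `threshold_m`, `n_gaps`, `total_area_m2`,
#'   `pct_of_study_area`.
#' @export
gapAreaByThreshold <- function(chm, thresholds = seq(2, 20, by = 2)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  pixArea <- gridResolution(chm)^2
  studyPix <- sum(!is.na(gridValues(chm)))
  rows <- lapply(thresholds, function(th) {
    lm <- labelGaps(chm, th)
    sizes <- gapSizes(lm)
    data.frame(threshold_m = th, n_gaps = length(sizes),
               total_area_m2 = sum(sizes) * pixArea,
               pct_of_study_area = 100 * sum(sizes) / studyPix)
  })
  do.call(rbind, rows)
}

#' Log pmf of the Zeta (discrete power law) distribution
#'
#' `log f(k) = -lambda * log(k) - log(zeta(lambda))` for integer sizes
#' `k >= 1`, where `zeta` is the Riemann zeta function (evaluated by
#' `pracma::zeta`, accurate to well below 1e-12 relative error over the
#' prior range used here).
#'
#' @param k integer gap sizes (>= 1).
#' @param lambda exponent (> 1; the normalizer diverges at 1).
#' @return numeric vector of log-probabilities.
#' @export
zetaLogPMF <- function(k, lambda) {
  if (any(k < 1) || any(abs(k - round(k)) > 1e-9))
    stop("k must be integers >= 1", call. = FALSE)
  if (length(lambda) != 1L || lambda <= 1)
    stop("lambda must be a single value > 1 (normalizer diverges at 1)",
         call. = FALSE)
  -lambda * log(k) - log(pracma::zeta(lambda))
}

#' Estimate the gap size-frequency exponent by Metropolis-Hastings MCMC
#'
#' Bayesian estimate of the Zeta exponent of a sample of gap sizes in
#' pixels, with a uniform prior on `(priorRange[1], priorRange[2])`. The
#' sampler is a random-walk Metropolis-Hastings chain: normal proposals
#' centred on the current value with fixed standard deviation; proposals
#' below 1 are replaced by a fresh draw from the same proposal density
#' (redraw-until-at-least-1), and proposals outside the prior support are
#' rejected through the zero prior density. The redraw rule makes the
#' proposal mildly asymmetric near the lower bound; no Hastings correction
#' is applied, deliberately reproducing the field's standard sampler rather
#' than an idealized one (the effect is negligible away from the boundary,
#' and the grid-posterior cross-check in the test suite bounds it).
#'
#' The retained sample count is exactly `(nTotal - nBurnin) / thin` (3800 at
#' the default chain of 100,000 with 5,000 burn-in and thinning by 25).
#'
#' @param sizes integer vector of gap sizes in pixels (>= 1 gap).
#' @param nTotal chain length (default 1e5).
#' @param nBurnin discarded initial iterations (default 5000).
#' @param thin keep every `thin`-th value after burn-in (default 25).
#' @param priorRange uniform prior support (default `c(1.01, 5)`).
#' @param proposalSd proposal standard deviation (default 0.1).
#' @param seed RNG seed; the initial value is drawn from the prior.
#' @return a [ZetaPosterior-class].
#' @export
estimateLambda <- function(sizes, nTotal = 100000L, nBurnin = 5000L,
                           thin = 25L, priorRange = c(1.01, 5),
                           proposalSd = 0.1, seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L) stop("need at least one gap size", call. = FALSE)
  if (any(sizes < 1L)) stop("gap sizes must be >= 1 pixel", call. = FALSE)
  nTotal <- as.integer(nTotal); nBurnin <- as.integer(nBurnin)
  thin <- as.integer(thin)
  if ((nTotal - nBurnin) %% thin != 0L)
    stop("(nTotal - nBurnin) must be a multiple of thin", call. = FALSE)
  n <- length(sizes)
  S <- sum(log(sizes))
  logLik <- function(l) -l * S - n * log(pracma::zeta(l))
  prMin <- priorRange[1]; prMax <- priorRange[2]
  chain <- numeric(nTotal)
  nAccept <- 0L
  withSeed(seed, {
    cur <- stats::runif(1, prMin, prMax)
    curLL <- logLik(cur)
    for (i in seq_len(nTotal)) {
      prop <- stats::rnorm(1, cur, proposalSd)
      while (prop < 1) prop <- stats::rnorm(1, cur, proposalSd)
      if (prop >= prMin && prop <= prMax) {
        propLL <- logLik(prop)
        if (log(stats::runif(1)) < propLL - curLL) {
          cur <- prop; curLL <- propLL; nAccept <- nAccept + 1L
        }
      }
      chain[i] <- cur
    }
  })
  retained <- chain[seq(nBurnin + thin, nTotal, by = thin)]
  cri <- as.numeric(stats::quantile(retained, c(0.025, 0.975)))
  new("ZetaPosterior", chain = retained,
      lambdaMedian = stats::median(retained), cri = cri,
      settings = list(nTotal = nTotal, nBurnin = nBurnin, thin = thin,
                      priorMin = prMin, priorMax = prMax,
                      proposalSd = proposalSd, seed = seed),
      nSizes = as.integer(n), acceptanceRate = nAccept / nTotal)
}

#' Compare two gap size-frequency exponents
#'
#' Reports the difference of posterior medians (post minus pre) and flags
#' the change as significant when the two 95\% credible intervals do not
#' overlap.
#'
#' @param pre,post [ZetaPosterior-class] objects (conventionally estimated
#'   at the same gap height threshold).
#' @return list with `deltaMedian`, `significant`, `criPre`, `criPost`.
#' @export
compareLambda <- function(pre, post) {
  criPre <- credibleInterval(pre)
  criPost <- credibleInterval(post)
  list(deltaMedian = lambdaMedian(post) - lambdaMedian(pre),
       significant = criPre[1] > criPost[2] || criPost[1] > criPre[2],
       criPre = criPre, criPost = criPost)
}
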