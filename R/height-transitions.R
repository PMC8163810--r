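#' @include canopy-rasters.R
NULL

## internal: height -> class index with half-open [c-1, c) bins; heights
## exactly at the top edge fall in the last class.
heightClass <- function(h, nClasses, width) {
  pmin(floor(h / width) + 1L, nClasses)
}

#' Build a canopy height-class transition matrix
#'
#' Counts, for every paired non-nodata pixel of two aligned rasters, the
#' transition from its initial to its final height class. Class `c` covers
#' `[c-1, c) * classWidthM` metres; the number of classes is the ceiling of
#' the maximum height over both epochs (at least 2), so heights exactly at
#' the overall maximum fall in the last class. Entry `[i, j]` counts pixels
#' starting in class `j` and ending in class `i`; column sums therefore
#' equal the per-class start counts.
#'
#' @param pre,post [HeightRaster-class] objects on the same grid
#'   (conventionally the 5 m mean-height grid, which has no empty pixels).
#' @param classWidthM height class width (m), default 1.
#' @return a [TransitionModel-class].
#' @export
buildTransitionMatrix <- function(pre, post, classWidthM = 1) {
  stopIfGeometryMismatch(pre, post, "height rasters")
  h0 <- as.vector(gridValues(pre))
  h1 <- as.vector(gridValues(post))
  ok <- !is.na(h0) & !is.na(h1)
  if (!any(ok)) stop("no paired non-nodata pixels", call. = FALSE)
  h0 <- h0[ok]; h1 <- h1[ok]
  if (any(h0 < -1e-9) || any(h1 < -1e-9))
    stop("heights must be >= 0", call. = FALSE)
  nClasses <- max(2L, as.integer(ceiling(max(h0, h1) / classWidthM)))
  i <- heightClass(h1, nClasses, classWidthM)   # end class
  j <- heightClass(h0, nClasses, classWidthM)   # start class
  counts <- matrix(0, nClasses, nClasses)
  tab <- table(factor(i, levels = seq_len(nClasses)),
               factor(j, levels = seq_len(nClasses)))
  counts[] <- as.numeric(tab)
  new("TransitionModel", counts = counts, classWidth = classWidthM,
      nClasses = nClasses, edges = seq(0, nClasses) * classWidthM)
}

## internal: column-normalize a count/probability matrix; columns with zero
## sum become uniform (with a warning when warnEmpty).
columnStochastic <- function(counts, warnEmpty = TRUE) {
  cs <- colSums(counts)
  P <- counts
  empty <- cs == 0
  if (any(empty)) {
    if (warnEmpty)
      warning(sum(empty), " empty start class(es) assigned a uniform column",
              call. = FALSE)
    P[, empty] <- 1 / nrow(counts)
    cs[empty] <- 1
  }
  sweep(P, 2, cs, "/")
}

## internal: dominant right eigenvector of a column-stochastic matrix.
## The dominant eigenvalue of a column-stochastic matrix is exactly 1; this
## is verified rather than silently renormalized.
dominantEigenvector <- function(P, tol = 1e-9) {
  e <- eigen(P)
  k <- which.max(Mod(e$values))
  if (abs(Mod(e$values[k]) - 1) > tol)
    stop(sprintf("dominant eigenvalue %.12f is not 1 within %g: matrix is not column-stochastic",
                 Mod(e$values[k]), tol), call. = FALSE)
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8 * max(abs(v))))
    stop("dominant eigenvector has mixed signs: multiple communicating classes",
         call. = FALSE)
  v <- pmax(v, 0)
  v / sum(v)
}

## internal: check irreducibility structure; errors listing closed blocks
## when more than one closed communicating class exists.
checkReducibility <- function(P) {
  g <- igraph::graph_from_adjacency_matrix(t(P) > 0, mode = "directed")
  scc <- igraph::components(g, mode = "strong")
  if (scc$no == 1L) return(invisible(TRUE))
  memb <- scc$membership
  closed <- vapply(seq_len(scc$no), function(cl) {
    from <- which(memb == cl)
    # closed iff no probability mass leaves the class
    all(P[-from, from, drop = FALSE] == 0)
  }, logical(1))
  if (sum(closed) > 1L) {
    blocks <- vapply(which(closed), function(cl)
      paste(which(memb == cl), collapse = ","), character(1))
    stop("transition matrix is reducible with multiple closed classes: {",
         paste(blocks, collapse = "} {"), "}", call. = FALSE)
  }
  invisible(TRUE)
}

#' Projected steady-state canopy height distribution
#'
#' Normalizes the transition counts column-wise to a column-stochastic
#' matrix and extracts its dominant right eigenvector — the height
#' distribution left unchanged by the observed transition dynamics, i.e.
#' the expected equilibrium if the disturbance-interval dynamics persisted
#' indefinitely. The eigenvalue is verified to be 1 within 1e-9. The mean
#' equilibrium height uses class midpoints (switchable to lower edges).
#'
#' @param model a [TransitionModel-class]; empty start classes receive a
#'   uniform column with a warning.
#' @param meanFrom `"midpoint"` (default) or `"edge"`: the class statistic
#'   used for the mean height.
#' @return a [SteadyState-class] point estimate (no posterior envelope).
#' @export
steadyState <- function(model, meanFrom = c("midpoint", "edge")) {
  meanFrom <- match.arg(meanFrom)
  P <- columnStochastic(model@counts)
  checkReducibility(P)
  x <- dominantEigenvector(P)
  stat <- classStat(model@edges, meanFrom)
  new("SteadyState", distribution = x,
      meanHeight = sum(x * stat),
      envLow = numeric(0), envHigh = numeric(0),
      meanHeightCI = numeric(0), nDraws = 0L, seed = NA_integer_,
      edges = model@edges)
}

## internal: per-class height statistic
classStat <- function(edges, meanFrom) {
  if (meanFrom == "midpoint") (edges[-1] + edges[-length(edges)]) / 2
  else edges[-length(edges)]
}

#' Dirichlet-multinomial posterior of the steady-state height distribution
#'
#' Each column of the transition matrix is a multinomial sample of its
#' start class; with the conjugate uninformative Dirichlet prior
#' (all concentration parameters 1, i.e. transitions a priori uniform over
#' height classes), the posterior of column `j` is
#' `Dirichlet(counts[, j] + 1)`. Each draw samples every column, computes
#' the stationary distribution of the sampled matrix, and the per-class
#' 2.5/97.5 percentiles over draws form the 95\% credible envelope; the
#' mean-height CI is taken over the per-draw means. Sampled columns are
#' strictly positive, so every draw is irreducible; a draw failing the
#' eigenvalue check is redrawn (bounded retries).
#'
#' @param model a [TransitionModel-class].
#' @param nDraws number of posterior draws (default 10000).
#' @param seed RNG seed.
#' @param meanFrom class statistic for the mean, as in [steadyState()].
#' @return a [SteadyState-class] with posterior envelope. The point
#'   estimate (`stationaryDistribution`) is the eigenvector of the
#'   posterior-mean transition matrix (counts + 1, column-normalized):
#'   strictly positive and hence always well defined, unlike the
#'   raw-count matrix of [steadyState()], which sparse data can make
#'   reducible or absorbing; with well-populated counts the two agree to
#'   the order of one pseudo-count per column.
#' @export
steadyStatePosterior <- function(model, nDraws = 10000L, seed = 1L,
                                 meanFrom = c("midpoint", "edge")) {
  meanFrom <- match.arg(meanFrom)
  nDraws <- as.integer(nDraws)
  # Bayesian point estimate: stationary distribution of the posterior-mean
  # transition matrix (counts + 1 column-normalized). Strictly positive,
  # hence always irreducible — unlike the raw-count matrix, which sparse
  # data can make reducible or absorbing (see steadyState) — and central in
  # the posterior, so the envelope brackets it.
  Pmean <- sweep(model@counts + 1, 2, colSums(model@counts + 1), "/")
  xPoint <- dominantEigenvector(Pmean)
  statPoint <- classStat(model@edges, meanFrom)
  point <- new("SteadyState", distribution = xPoint,
               meanHeight = sum(xPoint * statPoint),
               envLow = numeric(0), envHigh = numeric(0),
               meanHeightCI = numeric(0), nDraws = 0L, seed = NA_integer_,
               edges = model@edges)
  nC <- model@nClasses
  alpha <- model@counts + 1
  stat <- classStat(model@edges, meanFrom)
  draws <- matrix(NA_real_, nC, nDraws)
  means <- numeric(nDraws)
  withSeed(seed, {
    for (d in seq_len(nDraws)) {
      x <- NULL
      for (try in seq_len(10L)) {
        G <- matrix(stats::rgamma(nC * nC, shape = alpha), nC, nC)
        P <- sweep(G, 2, colSums(G), "/")
        x <- tryCatch(dominantEigenvector(P), error = function(e) NULL)
        if (!is.null(x)) break
      }
      if (is.null(x))
        stop("posterior draw repeatedly failed the stationarity check",
             call. = FALSE)
      draws[, d] <- x
      means[d] <- sum(x * stat)
    }
  })
  env <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE)
  new("SteadyState", distribution = point@distribution,
      meanHeight = point@meanHeight,
      envLow = env[1L, ], envHigh = env[2L, ],
      meanHeightCI = as.numeric(stats::quantile(means, c(0.025, 0.975))),
      nDraws = nDraws, seed = as.integer(seed), edges = model@edges)
}

#' Observed height distribution on a class grid
#'
#' Histogram of raster heights using the same half-open class convention as
#' [buildTransitionMatrix()], normalized to probabilities.
#'
#' @param raster a [HeightRaster-class].
#' @param nClasses number of classes.
#' @param classWidthM class width (m).
#' @return numeric probability vector of length `nClasses`.
#' @export
heightDistribution <- function(raster, nClasses, classWidthM = 1) {
  h <- as.vector(gridValues(raster))
  h <- h[!is.na(h)]
  cls <- heightClass(h, nClasses, classWidthM)
  tabulate(cls, nbins = nClasses) / length(h)
}

#' Compare an observed height distribution with a projected equilibrium
#'
#' Reports the mean-height difference (projected minus observed) and the
#' total-variation distance between the two distributions, and flags a
#' departure from steady state when the observed mean lies outside the
#' projected mean's 95\% credible interval (requires a posterior
#' [SteadyState-class]; `NA` otherwise).
#'
#' @param observed numeric probability vector on the same class grid as
#'   `projected`.
#' @param projected a [SteadyState-class].
#' @param meanFrom class statistic for the observed mean (as in
#'   [steadyState()]).
#' @return list with `meanObserved`, `meanProjected`, `meanDiff`,
#'   `tvDistance`, `departure`.
#' @export
compareDistributions <- function(observed, projected,
                                 meanFrom = c("midpoint", "edge")) {
  meanFrom <- match.arg(meanFrom)
  p <- stationaryDistribution(projected)
  if (length(observed) != length(p))
    stop("distributions must share the class grid", call. = FALSE)
  if (abs(sum(observed) - 1) > 1e-9)
    stop("observed must be a probability vector", call. = FALSE)
  stat <- classStat(classEdges(projected), meanFrom)
  mObs <- sum(observed * stat)
  ci <- credibleInterval(projected)
  list(meanObserved = mObs,
       meanProjected = meanCanopyHeight(projected),
       meanDiff = meanCanopyHeight(projected) - mObs,
       tvDistance = 0.5 * sum(abs(p - observed)),
       departure = if (length(ci) == 2L) (mObs < ci[1] || mObs > ci[2])
                   else NA)
}
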