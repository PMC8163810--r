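# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (flood fill, grid enumeration, power iteration,
# scalar loops) so they share no code path with the implementation.

# brute-force 8-connectivity flood fill on a logical matrix; returns an
# integer label matrix (0 = background)
floodFillLabels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nextLab <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || labels[r0, c0] > 0L) next
    nextLab <- nextLab + 1L
    stack <- list(c(r0, c0))
    labels[r0, c0] <- nextLab
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- cur[1] + dr; c <- cur[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- nextLab
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  labels
}

# normalized grid posterior for the Zeta exponent under a uniform prior;
# returns the posterior median by direct enumeration
gridPosteriorMedian <- function(sizes, step = 0.001, lo = 1.01, hi = 5) {
  grid <- seq(lo, hi, by = step)
  n <- length(sizes); S <- sum(log(sizes))
  ll <- -grid * S - n * log(pracma::zeta(grid))
  w <- exp(ll - max(ll))
  cdf <- cumsum(w) / sum(w)
  grid[which(cdf >= 0.5)[1]]
}

# stationary distribution by repeated application of the column-stochastic
# matrix until the L1 change is below tol
powerIterationStationary <- function(P, tol = 1e-13, maxIter = 1e6) {
  x <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(maxIter)) {
    xNew <- as.vector(P %*% x)
    xNew <- xNew / sum(xNew)
    if (sum(abs(xNew - x)) < tol) return(xNew)
    x <- xNew
  }
  stop("power iteration did not converge")
}

# sum-to-one constrained least squares by substitution: eliminate the last
# fraction and solve the reduced unconstrained problem
constrainedLSOracle <- function(E, r) {
  m <- ncol(E)
  A <- E[, -m, drop = FALSE] - E[, m]
  fRed <- solve(crossprod(A), crossprod(A, r - E[, m]))
  c(fRed, 1 - sum(fRed))
}

# random strictly positive column-stochastic matrix (always irreducible)
randomStochasticMatrix <- function(n) {
  M <- matrix(stats::runif(n * n, 0.01, 1), n, n)
  sweep(M, 2, colSums(M), "/")
}

# small helper: uniform height raster
uniformCHM <- function(h, nr = 8, nc = 8, res = 1.25) {
  heightRaster(matrix(h, nr, nc), resolution = res)
}
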