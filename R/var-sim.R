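#' @include AllClasses.R simulate.R
NULL

# companion matrix of a list of 2x2 lag-coefficient matrices
companionMatrix <- function(A) {
  p <- length(A)
  C <- matrix(0, 2 * p, 2 * p)
  for (l in seq_len(p)) C[1:2, (2 * l - 1):(2 * l)] <- A[[l]]
  if (p > 1) C[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  C
}

#' Spectral radius of the companion matrix of a VAR model
#'
#' A VAR(p) model is stable exactly when this radius is below 1.
#'
#' @param A list of p 2x2 lag-coefficient matrices.
#' @return The largest eigenvalue modulus of the companion matrix.
#' @export
varSpectralRadius <- function(A) {
  max(Mod(eigen(companionMatrix(A), only.values = TRUE)$values))
}

# draw one stable random VAR(p): entries uniform on [-1,1]/p, rejected
# until the companion spectral radius is below radiusCap
randomStableVar <- function(p, radiusCap = 0.95, maxAttempts = 1000L) {
  for (i in seq_len(maxAttempts)) {
    A <- replicate(p, matrix(stats::runif(4, -1, 1) / p, 2, 2),
                   simplify = FALSE)
    if (varSpectralRadius(A) < radiusCap) return(A)
  }
  stop(sprintf("no stable VAR(%d) model found in %d attempts", p,
               maxAttempts))
}

#' Generate correlated stationary VAR(p) timeseries pairs
#'
#' Each pair follows a randomly generated stable bivariate
#' vector-autoregression of random order p drawn from `orderRange`, with
#' innovation covariance having off-diagonal `rho * sigmaX * sigmaY`
#' (innovation variances drawn from `varRange`) and intercepts chosen so
#' the implied process mean \eqn{\mu = (I - A_1 - \dots - A_p)^{-1}\nu}
#' lies in `meanRange`. Coefficient matrices are drawn entrywise uniformly
#' on \[-1, 1\]/p and rejected until the companion-matrix spectral radius
#' is below 0.95; each realization is preceded by a discarded burn-in.
#'
#' @inheritParams generateWhitePairs
#' @param orderRange integer range of admissible VAR orders (within 1..3).
#' @param radiusCap stability rejection threshold on the companion spectral
#'   radius (below 1; the margin avoids near-unit-root burn-in pathology).
#' @return A [PairDataset-class] at stage `"stationary"`; the realized
#'   models (orders, coefficient lists, intercepts, innovation variances)
#'   are stored in `@groundTruth`.
#' @export
generateVarPairs <- function(nPairs, T = 500L, rho = 0.3,
                             orderRange = c(1L, 3L),
                             meanRange = c(-100, 100),
                             varRange = c(0, 10),
                             sliceX = 0L, sliceY = 1L,
                             radiusCap = 0.95, seed = NULL) {
  if (nPairs < 1) stop("'nPairs' must be at least 1")
  if (min(orderRange) < 1 || max(orderRange) > 3)
    stop("'orderRange' must lie within [1, 3]")
  if (!is.null(seed)) set.seed(seed)

  orders <- sample(seq(min(orderRange), max(orderRange)), nPairs,
                   replace = TRUE)
  models <- vector("list", nPairs)
  vX <- varRange[1] + (varRange[2] - varRange[1]) * stats::runif(nPairs)
  vY <- varRange[1] + (varRange[2] - varRange[1]) * stats::runif(nPairs)
  muX <- stats::runif(nPairs, meanRange[1], meanRange[2])
  muY <- stats::runif(nPairs, meanRange[1], meanRange[2])
  radii <- numeric(nPairs)
  for (i in seq_len(nPairs)) {
    A <- randomStableVar(orders[i], radiusCap = radiusCap)
    Asum <- Reduce(`+`, A)
    nu <- as.numeric((diag(2) - Asum) %*% c(muX[i], muY[i]))
    radii[i] <- varSpectralRadius(A)
    models[[i]] <- list(order = orders[i], A = A, intercept = nu,
                        mean = c(muX[i], muY[i]),
                        sigmaXSq = vX[i], sigmaYSq = vY[i], rho = rho,
                        radius = radii[i])
  }

  x <- matrix(0, T, nPairs)
  y <- matrix(0, T, nPairs)
  # simulate order-groups jointly: per time step, vectorized across pairs
  for (p in sort(unique(orders))) {
    idx <- which(orders == p)
    n <- length(idx)
    burn <- max(500L, ceiling(10 * p / (1 - max(radii[idx]))))
    total <- burn + T
    # coefficient arrays: a[r, c, lag, pair]
    a <- array(0, c(2, 2, p, n))
    nu <- matrix(0, 2, n)
    for (j in seq_len(n)) {
      m <- models[[idx[j]]]
      for (l in seq_len(p)) a[, , l, j] <- m$A[[l]]
      nu[, j] <- m$intercept
    }
    sx <- sqrt(vX[idx]); sy <- sqrt(vY[idx])
    lag <- array(0, c(2, p, n))     # lag buffer, most recent first
    lag[1, , ] <- rep(muX[idx], each = p)
    lag[2, , ] <- rep(muY[idx], each = p)
    keep1 <- matrix(0, T, n); keep2 <- matrix(0, T, n)
    for (t in seq_len(total)) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      e1 <- sx * z1
      e2 <- sy * (rho * z1 + sqrt(1 - rho^2) * z2)
      new1 <- nu[1, ] + e1
      new2 <- nu[2, ] + e2
      for (l in seq_len(p)) {
        new1 <- new1 + a[1, 1, l, ] * lag[1, l, ] + a[1, 2, l, ] * lag[2, l, ]
        new2 <- new2 + a[2, 1, l, ] * lag[1, l, ] + a[2, 2, l, ] * lag[2, l, ]
      }
      if (p > 1) lag[, 2:p, ] <- lag[, 1:(p - 1), ]
      lag[1, 1, ] <- new1
      lag[2, 1, ] <- new2
      if (t > burn) {
        keep1[t - burn, ] <- new1
        keep2[t - burn, ] <- new2
      }
    }
    x[, idx] <- keep1
    y[, idx] <- keep2
  }

  new("PairDataset", x = x, y = y,
      sliceX = as.integer(sliceX), sliceY = as.integer(sliceY),
      stage = "stationary", stationaryX = x, stationaryY = y,
      powerX = NULL, powerY = NULL,
      groundTruth = list(model = "var", rho = rho, muX = muX, muY = muY,
                         varX = vX, varY = vY, orders = orders,
                         models = models))
}
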