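#' @include AllClasses.R AllGenerics.R theory.R distributions.R
NULL

#' Sample a slice power process
#'
#' Draws T independent per-timepoint power values
#' \eqn{\sigma^2_{m,t} \sim IG(shape, scale)}: the realized time-varying
#' signal power of one slice.
#'
#' @param spec a [PowerProcessSpec-class].
#' @param T number of time points.
#' @param seed optional integer seed; for a fixed seed the realized series
#'   is reproduced exactly.
#' @return A strictly positive numeric vector of length T.
#' @examples
#' p <- samplePowerProcess(PowerProcessSpec(3, 2), T = 100, seed = 1)
#' all(p > 0)
#' @export
samplePowerProcess <- function(spec, T, seed = NULL) {
  stopifnot(is(spec, "PowerProcessSpec"))
  validObject(spec)
  if (T < 1) stop("'T' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  rinvgamma(T, shape = spec@shape, scale = spec@scale)
}

#' Generate correlated stationary white timeseries pairs
#'
#' Each pair is drawn iid over time from a bivariate normal with underlying
#' correlation `rho`; per-pair means are drawn uniformly from `meanRange`
#' and per-pair stationary signal variances uniformly from `varRange`.
#' Defaults are the simulation protocol used throughout the package:
#' 2,000 pairs, T = 500, rho = 0.3, means in \[-100, 100\], variances in
#' (0, 10\].
#'
#' @param nPairs number of pairs.
#' @param T series length (at least 3).
#' @param rho underlying correlation, |rho| < 1.
#' @param meanRange range the per-pair means are drawn from (set to
#'   `c(0, 0)` for zero-mean signals matching the analytic model).
#' @param varRange range the per-pair variances are drawn from; the lower
#'   end is open.
#' @param sliceX,sliceY slice labels assigned to the x and y members.
#' @param seed optional integer seed.
#' @return A [PairDataset-class] at stage `"stationary"` with per-pair
#'   ground truth in `@groundTruth`.
#' @examples
#' ds <- generateWhitePairs(200, T = 100, seed = 1)
#' mean(pairCorrelations(ds))
#' @export
generateWhitePairs <- function(nPairs, T = 500L, rho = 0.3,
                               meanRange = c(-100, 100),
                               varRange = c(0, 10),
                               sliceX = 0L, sliceY = 1L, seed = NULL) {
  if (nPairs < 1) stop("'nPairs' must be at least 1")
  if (T < 3) stop("'T' must be at least 3")
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  if (diff(range(varRange)) < 0 || max(varRange) <= 0)
    stop("'varRange' must be a non-empty range of positive variances")
  if (!is.null(seed)) set.seed(seed)
  muX <- stats::runif(nPairs, meanRange[1], meanRange[2])
  muY <- stats::runif(nPairs, meanRange[1], meanRange[2])
  # open lower end: draw on (0, 1] then rescale
  vX <- varRange[1] + (varRange[2] - varRange[1]) * stats::runif(nPairs)
  vY <- varRange[1] + (varRange[2] - varRange[1]) * stats::runif(nPairs)
  z1 <- matrix(stats::rnorm(T * nPairs), T, nPairs)
  z2 <- matrix(stats::rnorm(T * nPairs), T, nPairs)
  x <- sweep(sweep(z1, 2, sqrt(vX), `*`), 2, muX, `+`)
  ycore <- rho * z1 + sqrt(1 - rho^2) * z2
  y <- sweep(sweep(ycore, 2, sqrt(vY), `*`), 2, muY, `+`)
  new("PairDataset", x = x, y = y,
      sliceX = as.integer(sliceX), sliceY = as.integer(sliceY),
      stage = "stationary", stationaryX = x, stationaryY = y,
      powerX = NULL, powerY = NULL,
      groundTruth = list(model = "white", rho = rho, muX = muX, muY = muY,
                         varX = vX, varY = vY))
}

#' Weight a stationary pair dataset by slice power processes
#'
#' Multiplies every x series by the square root of the slice-m power series
#' and every y series by the square root of the slice-n power series,
#' producing non-stationary pairs. One shared power series per slice is
#' used, mirroring simultaneous acquisition of all voxels in a slice. The
#' stationary originals are retained for oracle comparisons.
#'
#' @param ds a [PairDataset-class] at stage `"stationary"`.
#' @param powerX,powerY either strictly positive numeric power series of
#'   length T, or [PowerProcessSpec-class] objects from which one shared
#'   series per slice is sampled.
#' @param seed optional integer seed used when specs are supplied.
#' @return A [PairDataset-class] at stage `"weighted"` carrying the
#'   realized power series.
#' @export
applyPowerWeighting <- function(ds, powerX, powerY, seed = NULL) {
  stopifnot(is(ds, "PairDataset"))
  if (ds@stage != "stationary")
    stop("power weighting requires a stage 'stationary' dataset")
  T <- nrow(ds@x)
  if (!is.null(seed)) set.seed(seed)
  specs <- list(x = NULL, y = NULL)
  if (is(powerX, "PowerProcessSpec")) {
    specs$x <- powerX
    powerX <- samplePowerProcess(powerX, T)
  }
  if (is(powerY, "PowerProcessSpec")) {
    specs$y <- powerY
    powerY <- samplePowerProcess(powerY, T)
  }
  if (length(powerX) != T || length(powerY) != T)
    stop("power series length must match the series length T")
  if (any(powerX <= 0) || any(powerY <= 0))
    stop("power series must be strictly positive")
  gt <- ds@groundTruth
  gt$powerSpecX <- specs$x
  gt$powerSpecY <- specs$y
  new("PairDataset",
      x = ds@x * sqrt(powerX), y = ds@y * sqrt(powerY),
      sliceX = ds@sliceX, sliceY = ds@sliceY, stage = "weighted",
      stationaryX = ds@stationaryX, stationaryY = ds@stationaryY,
      powerX = powerX, powerY = powerY, groundTruth = gt)
}

#' Per-pair Pearson correlations of a pair dataset
#'
#' @param ds a [PairDataset-class].
#' @return Numeric vector of length `nPairs(ds)`: the sample correlation of
#'   each (x, y) pair at the dataset's current stage.
#' @export
pairCorrelations <- function(ds) {
  stopifnot(is(ds, "PairDataset"))
  colCorr(ds@x, ds@y)
}

# columnwise Pearson correlation of two equally shaped matrices
colCorr <- function(a, b) {
  a <- sweep(a, 2, colMeans(a), `-`)
  b <- sweep(b, 2, colMeans(b), `-`)
  colSums(a * b) / sqrt(colSums(a^2) * colSums(b^2))
}
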