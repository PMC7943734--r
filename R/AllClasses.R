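#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Inverse-gamma specification of a slice power process
#'
#' Describes the time-varying signal power of one EPI slice: the squared
#' multiplicative weight applied to every voxel of slice \eqn{m} at time
#' \eqn{t} is drawn, independently across time, from an inverse-gamma law
#' \eqn{\sigma^2_{m,t} \sim IG(\alpha_m, s_m)} with shape \eqn{\alpha_m} and
#' scale \eqn{s_m}. The mean power \eqn{s_m/(\alpha_m - 1)} is finite only
#' for \eqn{\alpha_m > 1}.
#'
#' @slot slice integer slice label (0-based in all tabular output).
#' @slot shape positive shape parameter \eqn{\alpha_m} (dimensionless).
#' @slot scale positive scale parameter \eqn{s_m} (signal-power units).
#'
#' @seealso [PowerProcessSpec()], [igMoment()], [samplePowerProcess()]
#' @export
setClass("PowerProcessSpec",
  representation(slice = "integer", shape = "numeric", scale = "numeric"))

setValidity("PowerProcessSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    msg <- c(msg, "'shape' must be a single positive finite number")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "'scale' must be a single positive finite number")
  if (length(object@slice) != 1L)
    msg <- c(msg, "'slice' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a PowerProcessSpec
#'
#' @param shape positive inverse-gamma shape \eqn{\alpha_m}.
#' @param scale positive inverse-gamma scale \eqn{s_m}. A rate
#'   parameterization \eqn{IG(\alpha, 1/\beta)} with rate \eqn{\beta}
#'   corresponds to `scale = 1/beta`.
#' @param slice integer slice label the process is attached to.
#' @return A [PowerProcessSpec-class] object.
#' @examples
#' sp <- PowerProcessSpec(shape = 3, scale = 2)
#' igMoment(sp, order = 1) # mean power = scale/(shape-1) = 1
#' @export
PowerProcessSpec <- function(shape, scale, slice = 0L) {
  new("PowerProcessSpec", slice = as.integer(slice),
      shape = as.numeric(shape), scale = as.numeric(scale))
}

setMethod("show", "PowerProcessSpec", function(object) {
  cat(sprintf("PowerProcessSpec: slice %d, IG(shape = %g, scale = %g)\n",
              object@slice, object@shape, object@scale))
  if (object@shape > 1)
    cat(sprintf("  mean power: %g\n", object@scale / (object@shape - 1)))
  else
    cat("  mean power: undefined (shape <= 1)\n")
})

#' Theoretical consequences of non-stationary power for sample correlation
#'
#' Holds the attenuation factor \eqn{\kappa}, the expected attenuated
#' correlation \eqn{\kappa\rho}, and the approximate sampling variance
#' \eqn{(1 - \kappa^2\rho^2)/(T - 2)} of sample correlation between two
#' timeseries weighted by slice power processes.
#'
#' @slot kappa attenuation factor, in (0, 1] for positive weight processes.
#' @slot expectedCorr \eqn{\kappa \rho}, the expected non-stationary
#'   correlation.
#' @slot corrSamplingVariance approximate variance of sample correlation.
#' @slot rho underlying stationary correlation.
#' @slot seriesLength series length T used for the variance.
#' @seealso [attenuation()]
#' @export
setClass("AttenuationResult",
  representation(kappa = "numeric", expectedCorr = "numeric",
                 corrSamplingVariance = "numeric", rho = "numeric",
                 seriesLength = "integer"))

setValidity("AttenuationResult", function(object) {
  msg <- character()
  if (abs(object@kappa) > 1 + 1e-12)
    msg <- c(msg, "|kappa| must not exceed 1")
  if (abs(object@expectedCorr) > 1 + 1e-12)
    msg <- c(msg, "|expectedCorr| must not exceed 1")
  if (object@corrSamplingVariance < 0)
    msg <- c(msg, "'corrSamplingVariance' must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AttenuationResult", function(object) {
  cat("AttenuationResult\n")
  cat(sprintf("  kappa:                  %.6f\n", object@kappa))
  cat(sprintf("  expected correlation:   %.6f (rho = %g)\n",
              object@expectedCorr, object@rho))
  cat(sprintf("  var of sample corr:     %.3e (T = %d)\n",
              object@corrSamplingVariance, object@seriesLength))
})

#' Parameters of the generalized Student's-t voxel marginal
#'
#' The marginal of a zero-mean Gaussian whose variance is inverse-gamma
#' mixed is a location-scale Student's-t with location 0, degrees of freedom
#' twice the inverse-gamma shape, and squared scale
#' \eqn{(s/\alpha)\sigma_x^2}.
#'
#' @slot location location \eqn{\mu_t}.
#' @slot dof positive degrees of freedom \eqn{\nu_t}.
#' @slot scaleSq positive squared scale \eqn{\sigma_t^2}.
#' @seealso [marginalTParams()], [dGeneralizedT()]
#' @export
setClass("GeneralizedTParams",
  representation(location = "numeric", dof = "numeric", scaleSq = "numeric"))

setValidity("GeneralizedTParams", function(object) {
  msg <- character()
  if (object@dof <= 0) msg <- c(msg, "'dof' must be positive")
  if (object@scaleSq <= 0) msg <- c(msg, "'scaleSq' must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneralizedTParams", function(object) {
  cat(sprintf(
    "GeneralizedTParams: location %g, dof %g, scale^2 %g\n",
    object@location, object@dof, object@scaleSq))
})

#' Collection of simulated timeseries pairs with slice labels
#'
#' Columns of `x` and `y` are the two members of each simulated pair; all
#' `x` series share slice `sliceX` (and hence, once weighted, one realized
#' power series), all `y` series share slice `sliceY`. The pre-weighting
#' stationary series are retained for oracle comparisons, and the realized
#' power series are kept once weighting has been applied.
#'
#' @slot x,y T-by-nPairs numeric matrices (one column per pair member).
#' @slot sliceX,sliceY integer slice labels of the x and y members.
#' @slot stage one of `"stationary"`, `"weighted"`, `"corrected"`.
#' @slot stationaryX,stationaryY the stage-`"stationary"` series (equal to
#'   `x`/`y` until weighting is applied).
#' @slot powerX,powerY realized per-timepoint power series
#'   \eqn{\sigma^2_{m,t}} (NULL at stage `"stationary"`).
#' @slot groundTruth list of generating parameters (per-pair means,
#'   variances, underlying correlation, VAR coefficients where applicable).
#' @export
setClass("PairDataset",
  representation(x = "matrix", y = "matrix",
                 sliceX = "integer", sliceY = "integer",
                 stage = "character",
                 stationaryX = "matrix", stationaryY = "matrix",
                 powerX = "numericOrNULL", powerY = "numericOrNULL",
                 groundTruth = "list"))

setValidity("PairDataset", function(object) {
  msg <- character()
  if (!identical(dim(object@x), dim(object@y)))
    msg <- c(msg, "'x' and 'y' must have identical dimensions")
  if (!object@stage %in% c("stationary", "weighted", "corrected"))
    msg <- c(msg, "'stage' must be stationary, weighted or corrected")
  if (!is.null(object@powerX)) {
    if (length(object@powerX) != nrow(object@x))
      msg <- c(msg, "'powerX' length must equal series length T")
    if (any(object@powerX <= 0))
      msg <- c(msg, "'powerX' must be strictly positive")
  }
  if (!is.null(object@powerY)) {
    if (length(object@powerY) != nrow(object@y))
      msg <- c(msg, "'powerY' length must equal series length T")
    if (any(object@powerY <= 0))
      msg <- c(msg, "'powerY' must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairDataset", function(object) {
  cat(sprintf(
    "PairDataset: %d pairs, T = %d, stage = %s (slices %d/%d)\n",
    ncol(object@x), nrow(object@x), object@stage,
    object@sliceX, object@sliceY))
})

#' Per-slice cross-sectional variance series
#'
#' The unbiased sample variance of voxel intensities within one slice at
#' each time point: the empirical estimate of the slice's time-varying
#' signal power (up to the stationary-variance scale factor).
#'
#' @slot slice integer slice label.
#' @slot values numeric series \eqn{\hat\sigma^2_{m,1..T}}.
#' @slot nVoxels number of voxels (or series) per estimate.
#' @slot estimator label; `"unbiased"` (n-1 denominator).
#' @export
setClass("SliceVarianceSeries",
  representation(slice = "integer", values = "numeric",
                 nVoxels = "integer", estimator = "character"))

setValidity("SliceVarianceSeries", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "'values' must be non-negative")
  if (object@nVoxels < 2L) msg <- c(msg, "'nVoxels' must be at least 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SliceVarianceSeries", function(object) {
  cat(sprintf(
    "SliceVarianceSeries: slice %d, T = %d, %d voxels, mean %.4g\n",
    object@slice, length(object@values), object@nVoxels,
    mean(object@values)))
})

#' 4D BOLD volume with slice-axis convention
#'
#' A 4D intensity array (x, y, z, t) with an explicit acquisition slice
#' axis, an optional 3D brain mask, and pass-through NIfTI header metadata
#' for write-back.
#'
#' @slot data 4D numeric array.
#' @slot sliceAxis which spatial axis (1, 2 or 3) indexes acquisition
#'   slices; 3 for standard axial EPI.
#' @slot brainMask optional 3D logical array matching the spatial grid.
#' @slot header optional NIfTI header retained from [readBoldVolume()].
#' @seealso [BoldVolume()], [readBoldVolume()], [estimateSliceVariance()]
#' @export
setClass("BoldVolume",
  representation(data = "array", sliceAxis = "integer",
                 brainMask = "arrayOrNULL", header = "ANY"))

setValidity("BoldVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4D array (x, y, z, t)")
  else if (dim(object@data)[4L] < 4L)
    msg <- c(msg, "at least 4 time points are required")
  if (!object@sliceAxis %in% 1:3)
    msg <- c(msg, "'sliceAxis' must be 1, 2 or 3")
  if (!is.null(object@brainMask)) {
    if (!identical(dim(object@brainMask), dim(object@data)[1:3]))
      msg <- c(msg, "'brainMask' shape must equal the spatial grid")
    if (!is.logical(object@brainMask))
      msg <- c(msg, "'brainMask' must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BoldVolume
#'
#' @param data 4D numeric array ordered (x, y, z, t).
#' @param sliceAxis spatial axis indexing acquisition slices (default 3,
#'   axial).
#' @param brainMask optional 3D logical array.
#' @param header optional NIfTI header for write-back.
#' @return A [BoldVolume-class] object.
#' @export
BoldVolume <- function(data, sliceAxis = 3L, brainMask = NULL,
                       header = NULL) {
  if (!is.null(brainMask)) brainMask <- array(as.logical(brainMask),
                                              dim = dim(brainMask))
  new("BoldVolume", data = data, sliceAxis = as.integer(sliceAxis),
      brainMask = brainMask, header = header)
}

setMethod("show", "BoldVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldVolume: %d x %d x %d spatial, T = %d, slice axis %d\n",
              d[1], d[2], d[3], d[4], object@sliceAxis))
  if (!is.null(object@brainMask))
    cat(sprintf("  brain mask: %d in-mask voxels\n", sum(object@brainMask)))
})

#' Seed-voxel connectivity map with Fisher-z significance
#'
#' @slot rMap 3D array of per-voxel Pearson correlations with the seed
#'   (NA outside the mask or for dropped zero-variance voxels).
#' @slot zMap Fisher-transformed map, atanh(r).
#' @slot sigMask 3D logical array of Bonferroni-significant voxels.
#' @slot alpha significance level before correction.
#' @slot nTests number of in-mask voxels tested.
#' @slot effectiveDf degrees of freedom used in the z variance.
#' @slot threshold two-sided critical value on the standardized z scale.
#' @slot nSaturated number of |r| = 1 voxels flagged significant with
#'   infinite z.
#' @slot nDropped number of zero-variance voxels dropped from the map.
#' @export
setClass("ConnectivityMap",
  representation(rMap = "array", zMap = "array", sigMask = "array",
                 alpha = "numeric", nTests = "integer",
                 effectiveDf = "numeric", threshold = "numeric",
                 nSaturated = "integer", nDropped = "integer"))

setValidity("ConnectivityMap", function(object) {
  msg <- character()
  r <- object@rMap[is.finite(object@rMap)]
  if (length(r) && max(abs(r)) > 1 + 1e-12)
    msg <- c(msg, "|r| must not exceed 1")
  if (!identical(dim(object@rMap), dim(object@sigMask)))
    msg <- c(msg, "'rMap' and 'sigMask' must share dimensions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConnectivityMap", function(object) {
  cat(sprintf(
    "ConnectivityMap: %s, %d tests, df = %g, alpha = %g (Bonferroni)\n",
    paste(dim(object@rMap), collapse = " x "), object@nTests,
    object@effectiveDf, object@alpha))
  cat(sprintf("  significant voxels: %d (threshold |z*sqrt(df-3)| > %.3f)\n",
              sum(object@sigMask, na.rm = TRUE), object@threshold))
  if (object@nDropped > 0L)
    cat(sprintf("  dropped zero-variance voxels: %d\n", object@nDropped))
})
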