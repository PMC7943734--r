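#' @include AllClasses.R
NULL

#' Estimate per-slice cross-sectional variance over time
#'
#' For every slice and time point, the unbiased sample variance of voxel
#' intensities (or of all simulated series assigned to that slice). Under
#' the multiplicative power model the slice-variance series is proportional
#' to the generating power process \eqn{\sigma^2_{m,t}}, the
#' proportionality constant being the cross-sectional variance of the
#' stationary components.
#'
#' @param x a [BoldVolume-class] or [PairDataset-class].
#' @param ... method-specific arguments: `useMask` (BoldVolume; default
#'   TRUE, estimate within the brain mask when one is present).
#' @return A list of [SliceVarianceSeries-class], one per slice.
#' @examples
#' ds <- generateWhitePairs(50, T = 40, seed = 1)
#' sv <- estimateSliceVariance(ds)
#' sv[[1]]
#' @export
setGeneric("estimateSliceVariance",
           function(x, ...) standardGeneric("estimateSliceVariance"))

#' Precision-correct data for slice-dependent non-stationary power
#'
#' Divides every sample by the square root of its own slice's estimated
#' variance at its own time point. When the slice-variance estimate tracks
#' the true time-varying power, the corrected series equals the underlying
#' stationary series up to one constant factor per slice, so pairwise
#' correlations of the corrected data recover the stationary correlations.
#'
#' @param x a [BoldVolume-class] or [PairDataset-class].
#' @param sliceVars list of [SliceVarianceSeries-class] covering every
#'   slice present in `x` (e.g. from [estimateSliceVariance()], or the true
#'   power series for oracle analyses).
#' @param ... method-specific arguments: `floor` (default `1e-12`), the
#'   variance floor below which correction aborts with an error rather than
#'   silently clamping.
#' @return An object of the same class as `x`, corrected.
#' @examples
#' ds <- generateWhitePairs(100, T = 60, seed = 1)
#' w <- applyPowerWeighting(ds, PowerProcessSpec(2, 2), PowerProcessSpec(3, 2),
#'                          seed = 2)
#' cd <- precisionCorrect(w, estimateSliceVariance(w))
#' mean(pairCorrelations(cd))
#' @export
setGeneric("precisionCorrect",
           function(x, sliceVars, ...) standardGeneric("precisionCorrect"))

#' Accessors for slicevar classes
#'
#' Small read-only accessors: `attenuationKappa` the attenuation factor;
#' `expectedCorr` the expected attenuated correlation; `stage` the
#' simulation stage of a [PairDataset-class]; `nPairs` and `seriesLength`
#' its dimensions; `sliceIndex`, `varianceValues` and `nVoxels` the fields
#' of a [SliceVarianceSeries-class]; `boldData`, `sliceAxis` and
#' `brainMask` the fields of a [BoldVolume-class]; `rMap`, `zMap` and
#' `sigMask` the maps of a [ConnectivityMap-class].
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("attenuationKappa",
           function(object) standardGeneric("attenuationKappa"))
#' @rdname accessors
#' @export
setGeneric("expectedCorr", function(object) standardGeneric("expectedCorr"))
#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setGeneric("seriesLength", function(object) standardGeneric("seriesLength"))
#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(object) standardGeneric("sliceIndex"))
#' @rdname accessors
#' @export
setGeneric("varianceValues",
           function(object) standardGeneric("varianceValues"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("boldData", function(object) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("sliceAxis", function(object) standardGeneric("sliceAxis"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("rMap", function(object) standardGeneric("rMap"))
#' @rdname accessors
#' @export
setGeneric("zMap", function(object) standardGeneric("zMap"))
#' @rdname accessors
#' @export
setGeneric("sigMask", function(object) standardGeneric("sigMask"))

setMethod("attenuationKappa", "AttenuationResult",
          function(object) object@kappa)
setMethod("expectedCorr", "AttenuationResult",
          function(object) object@expectedCorr)
setMethod("stage", "PairDataset", function(object) object@stage)
setMethod("nPairs", "PairDataset", function(object) ncol(object@x))
setMethod("seriesLength", "PairDataset", function(object) nrow(object@x))
setMethod("sliceIndex", "SliceVarianceSeries", function(object) object@slice)
setMethod("varianceValues", "SliceVarianceSeries",
          function(object) object@values)
setMethod("nVoxels", "SliceVarianceSeries", function(object) object@nVoxels)
setMethod("boldData", "BoldVolume", function(object) object@data)
setMethod("sliceAxis", "BoldVolume", function(object) object@sliceAxis)
setMethod("brainMask", "BoldVolume", function(object) object@brainMask)
setMethod("rMap", "ConnectivityMap", function(object) object@rMap)
setMethod("zMap", "ConnectivityMap", function(object) object@zMap)
setMethod("sigMask", "ConnectivityMap", function(object) object@sigMask)
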