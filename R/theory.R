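#' @include AllClasses.R AllGenerics.R
NULL

#' Fractional moments of an inverse-gamma power process
#'
#' Closed-form moments of \eqn{\sigma^2 \sim IG(\alpha, s)} needed by the
#' attenuation factor: the mean power \eqn{E[\sigma^2] = s/(\alpha-1)}
#' (order 1) and the mean weight
#' \eqn{E[\sigma] = \sqrt{s}\,\Gamma(\alpha - 1/2)/\Gamma(\alpha)}
#' (order 1/2). Gamma ratios are evaluated in log space so large shapes do
#' not overflow.
#'
#' @param spec a [PowerProcessSpec-class].
#' @param order `1` for \eqn{E[\sigma^2]} or `1/2` for \eqn{E[\sigma]}.
#' @return The moment \eqn{E[(\sigma^2)^{order}]}.
#' @examples
#' igMoment(PowerProcessSpec(3, 2), 1)    # 1
#' igMoment(PowerProcessSpec(2, 2), 1/2)  # sqrt(2)*gamma(1.5)/gamma(2)
#' @export
igMoment <- function(spec, order) {
  stopifnot(is(spec, "PowerProcessSpec"))
  validObject(spec)
  if (!(length(order) == 1L && order %in% c(0.5, 1)))
    stop("'order' must be 1/2 or 1")
  if (spec@shape <= order)
    stop(sprintf(
      "moment of order %g undefined: shape = %g must exceed the order",
      order, spec@shape))
  if (order == 1) spec@scale / (spec@shape - 1)
  else exp(0.5 * log(spec@scale) + lgamma(spec@shape - 0.5) -
             lgamma(spec@shape))
}

#' Attenuation factor kappa of sample correlation under time-varying power
#'
#' The correlation between two timeseries weighted by slice power processes
#' equals the stationary correlation multiplied by
#' \eqn{\kappa = E[\sigma_m \sigma_n] / \sqrt{E[\sigma_m^2] E[\sigma_n^2]}},
#' which the Cauchy-Schwarz inequality bounds by 1 in magnitude. For
#' positive weights \eqn{\kappa \in (0, 1]}, with equality exactly when the
#' two weight processes are proportional almost surely (in particular, when
#' they are identical, or both constant).
#'
#' @param specM,specN [PowerProcessSpec-class] objects for the two slices;
#'   shapes must exceed 1 so all required moments exist.
#' @param independent if TRUE (default) the processes are independent and
#'   \eqn{E[\sigma_m \sigma_n] = E[\sigma_m] E[\sigma_n]}; if FALSE the two
#'   specs are taken to describe one common process
#'   (\eqn{\sigma_m = \sigma_n}), the Cauchy-Schwarz equality case.
#' @return kappa, a number in (0, 1].
#' @examples
#' kappaTheoretical(PowerProcessSpec(2, 2), PowerProcessSpec(3, 2))
#' kappaTheoretical(PowerProcessSpec(2, 2), PowerProcessSpec(2, 2),
#'                  independent = FALSE) # identical processes: exactly 1
#' @export
kappaTheoretical <- function(specM, specN, independent = TRUE) {
  if (!independent) {
    if (!isTRUE(all.equal(c(specM@shape, specM@scale),
                          c(specN@shape, specN@scale))))
      stop("dependent case requires identical process specifications")
    return(1)
  }
  num <- igMoment(specM, 0.5) * igMoment(specN, 0.5)
  den <- sqrt(igMoment(specM, 1) * igMoment(specN, 1))
  num / den
}

#' Empirical attenuation factor from estimated weight processes
#'
#' Time-averaging estimator
#' \eqn{\hat\kappa = \overline{\hat\sigma_m \hat\sigma_n} /
#' \sqrt{\overline{\hat\sigma^2_m}\,\overline{\hat\sigma^2_n}}} applied to
#' two per-timepoint variance series (e.g. slice-variance estimates), the
#' anticipated weighting of correlation between the two slices.
#'
#' @param varM,varN positive variance series (numeric vectors of equal
#'   length) or [SliceVarianceSeries-class] objects.
#' @return The estimated attenuation factor.
#' @export
kappaEmpirical <- function(varM, varN) {
  if (is(varM, "SliceVarianceSeries")) varM <- varM@values
  if (is(varN, "SliceVarianceSeries")) varN <- varN@values
  if (length(varM) != length(varN))
    stop("variance series must have equal length")
  if (any(varM < 0) || any(varN < 0))
    stop("variance series must be non-negative")
  mean(sqrt(varM) * sqrt(varN)) / sqrt(mean(varM) * mean(varN))
}

#' Expected correlation between power-weighted timeseries
#'
#' The expected sample correlation of two non-stationary (power-weighted)
#' timeseries is the underlying stationary correlation attenuated by kappa.
#'
#' @param rho underlying stationary correlation, in \[-1, 1\].
#' @param kappa attenuation factor, in \[-1, 1\].
#' @return `kappa * rho`; its magnitude never exceeds `|rho|`.
#' @export
expectedNonstationaryCorr <- function(rho, kappa) {
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  if (abs(kappa) > 1) stop("'kappa' must lie in [-1, 1]")
  kappa * rho
}

#' Sampling variance of sample correlation under time-varying power
#'
#' Approximate variance \eqn{(1 - \kappa^2 \rho^2) / (T - 2)} of the sample
#' correlation between two power-weighted series of length T. Because
#' \eqn{\kappa \le 1}, this is never smaller than the stationary-signal
#' variance \eqn{(1 - \rho^2)/(T - 2)}: time-varying power inflates the
#' spread of correlation estimates and so promotes spurious connectivity.
#'
#' @param rho underlying stationary correlation.
#' @param kappa attenuation factor.
#' @param T series length, greater than 2.
#' @return The approximate sampling variance.
#' @export
varSampleCorr <- function(rho, kappa, T) {
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  if (abs(kappa) > 1) stop("'kappa' must lie in [-1, 1]")
  if (T <= 2) stop("'T' must exceed 2")
  (1 - kappa^2 * rho^2) / (T - 2)
}

#' Summarize the theoretical impact of two power processes on correlation
#'
#' Convenience wrapper combining [kappaTheoretical()],
#' [expectedNonstationaryCorr()] and [varSampleCorr()] into one
#' [AttenuationResult-class].
#'
#' @inheritParams kappaTheoretical
#' @param rho underlying stationary correlation.
#' @param T series length.
#' @return An [AttenuationResult-class].
#' @examples
#' attenuation(PowerProcessSpec(2, 2), PowerProcessSpec(3, 2),
#'             rho = 0.3, T = 500)
#' @export
attenuation <- function(specM, specN, rho, T, independent = TRUE) {
  k <- kappaTheoretical(specM, specN, independent = independent)
  new("AttenuationResult", kappa = k,
      expectedCorr = expectedNonstationaryCorr(rho, k),
      corrSamplingVariance = varSampleCorr(rho, k, T),
      rho = rho, seriesLength = as.integer(T))
}

#' Generalized Student's-t density of voxel intensity
#'
#' Marginal density of a voxel under the multiplicative power model: a
#' zero-mean Gaussian with stationary variance \eqn{\sigma_x^2} whose
#' variance is mixed over an inverse-gamma power process with shape
#' \eqn{\alpha} and scale \eqn{s} has density
#' \deqn{p(x) = \frac{\Gamma(\alpha + 1/2)}{\Gamma(\alpha)}
#'   (2\pi s \sigma_x^2)^{-1/2}
#'   \left(1 + \frac{x^2}{2 \sigma_x^2 s}\right)^{-(\alpha + 1/2)},}
#' a location-scale Student's-t with \eqn{\nu = 2\alpha} and squared scale
#' \eqn{(s/\alpha)\sigma_x^2}.
#'
#' @param x vector of quantiles.
#' @param shape inverse-gamma shape \eqn{\alpha > 0}.
#' @param igScale inverse-gamma scale \eqn{s > 0}.
#' @param sigmaXSq stationary signal variance \eqn{\sigma_x^2 > 0}.
#' @param log return the log density.
#' @return Density values.
#' @examples
#' dGeneralizedT(0, shape = 1, igScale = 1, sigmaXSq = 1) # gamma(1.5)/sqrt(2*pi)
#' @export
dGeneralizedT <- function(x, shape, igScale, sigmaXSq, log = FALSE) {
  if (shape <= 0 || igScale <= 0 || sigmaXSq <= 0)
    stop("'shape', 'igScale' and 'sigmaXSq' must be positive")
  ld <- lgamma(shape + 0.5) - lgamma(shape) -
    0.5 * base::log(2 * pi * igScale * sigmaXSq) -
    (shape + 0.5) * log1p(x^2 / (2 * sigmaXSq * igScale))
  if (log) ld else exp(ld)
}

#' Generalized-t parameters implied by a power-process specification
#'
#' Maps the model parameters to the location-scale Student's-t marginal of
#' voxel intensity: location 0, degrees of freedom `2 * shape`, squared
#' scale `(scale / shape) * sigmaXSq`.
#'
#' @param spec a [PowerProcessSpec-class].
#' @param sigmaXSq stationary signal variance.
#' @return A [GeneralizedTParams-class].
#' @examples
#' marginalTParams(PowerProcessSpec(3, 3), sigmaXSq = 1) # dof 6, scale^2 1
#' @export
marginalTParams <- function(spec, sigmaXSq) {
  stopifnot(is(spec, "PowerProcessSpec"))
  validObject(spec)
  if (sigmaXSq <= 0) stop("'sigmaXSq' must be positive")
  new("GeneralizedTParams", location = 0, dof = 2 * spec@shape,
      scaleSq = (spec@scale / spec@shape) * sigmaXSq)
}
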