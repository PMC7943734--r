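#' @include AllClasses.R
NULL

# Density/CDF helpers for families not shipped with stats. All densities
# accept a log argument and are vectorized in x.

#' Inverse-gamma distribution
#'
#' Density and distribution function of the inverse gamma with shape
#' `shape` and scale `scale`: if \eqn{X \sim IG(\alpha, s)} then
#' \eqn{1/X \sim Gamma(\alpha, rate = s)}.
#'
#' @param x,q vector of quantiles.
#' @param shape,scale positive parameters.
#' @param log,log.p logical; return log density / log probability.
#' @return `dinvgamma` the density, `pinvgamma` the CDF.
#' @export
dinvgamma <- function(x, shape, scale, log = FALSE) {
  ld <- ifelse(x > 0,
               shape * base::log(scale) - lgamma(shape) -
                 (shape + 1) * base::log(x) - scale / x,
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dinvgamma
#' @export
pinvgamma <- function(q, shape, scale, log.p = FALSE) {
  p <- stats::pgamma(1 / pmax(q, 0), shape = shape, rate = scale,
                     lower.tail = FALSE)
  p[q <= 0] <- 0
  if (log.p) base::log(p) else p
}

#' @rdname dinvgamma
#' @param n number of draws.
#' @export
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

# Laplace (double exponential), location mu, scale b
dlaplace <- function(x, location, scale, log = FALSE) {
  ld <- -abs(x - location) / scale - base::log(2 * scale)
  if (log) ld else exp(ld)
}

# Rayleigh, scale sigma
drayleigh <- function(x, scale, log = FALSE) {
  ld <- ifelse(x > 0,
               base::log(x) - 2 * base::log(scale) - x^2 / (2 * scale^2),
               -Inf)
  if (log) ld else exp(ld)
}

#' Location-scale Student's-t density
#'
#' Three-parameter Student's-t: `dt((x - location)/scale, df)/scale`.
#'
#' @param x vector of quantiles.
#' @param location location parameter.
#' @param scale positive scale parameter.
#' @param df positive degrees of freedom.
#' @param log return the log density.
#' @export
dlst <- function(x, location, scale, df, log = FALSE) {
  ld <- stats::dt((x - location) / scale, df = df, log = TRUE) -
    base::log(scale)
  if (log) ld else exp(ld)
}

plst <- function(q, location, scale, df) {
  stats::pt((q - location) / scale, df = df)
}
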