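#' @include AllClasses.R distributions.R
NULL

# ---- per-family maximum-likelihood fitters --------------------------------
# Each returns list(params, negLL, converged). Families with closed-form
# MLEs use them; the rest optimize the log-likelihood numerically from
# moment-based starting values. Positive-support families refuse
# non-positive samples.

fitGaussianML <- function(x) {
  mu <- mean(x); sd <- sqrt(mean((x - mu)^2))
  list(params = c(mean = mu, sd = sd),
       negLL = -sum(stats::dnorm(x, mu, sd, log = TRUE)), converged = TRUE)
}

fitExponentialML <- function(x) {
  rate <- 1 / mean(x)
  list(params = c(rate = rate),
       negLL = -sum(stats::dexp(x, rate, log = TRUE)), converged = TRUE)
}

fitRayleighML <- function(x) {
  s <- sqrt(mean(x^2) / 2)
  list(params = c(scale = s),
       negLL = -sum(drayleigh(x, s, log = TRUE)), converged = TRUE)
}

fitLogNormalML <- function(x) {
  lx <- log(x)
  mu <- mean(lx); sd <- sqrt(mean((lx - mu)^2))
  list(params = c(meanlog = mu, sdlog = sd),
       negLL = -sum(stats::dlnorm(x, mu, sd, log = TRUE)), converged = TRUE)
}

fitLaplaceML <- function(x) {
  m <- stats::median(x); b <- mean(abs(x - m))
  list(params = c(location = m, scale = b),
       negLL = -sum(dlaplace(x, m, b, log = TRUE)), converged = TRUE)
}

fitGammaML <- function(x) {
  mx <- mean(x); vx <- stats::var(x)
  start <- c(log(max(mx^2 / vx, 1e-3)), log(max(mx / vx, 1e-8)))
  nll <- function(p) {
    v <- suppressWarnings(
      -sum(stats::dgamma(x, shape = exp(p[1]), rate = exp(p[2]),
                         log = TRUE)))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(start, nll, method = "BFGS")
  list(params = c(shape = exp(opt$par[1]), rate = exp(opt$par[2])),
       negLL = opt$value, converged = opt$convergence == 0)
}

fitInvGammaML <- function(x) {
  # 1/X is gamma(shape, rate = scale): fit the reciprocals
  g <- fitGammaML(1 / x)
  shape <- unname(g$params["shape"]); scale <- unname(g$params["rate"])
  list(params = c(shape = shape, scale = scale),
       negLL = -sum(dinvgamma(x, shape, scale, log = TRUE)),
       converged = g$converged)
}

fitWeibullML <- function(x) {
  lx <- log(x)
  # profile likelihood in the shape k; scale has a closed form given k
  g <- function(k) sum(x^k * lx) / sum(x^k) - 1 / k - mean(lx)
  k <- tryCatch(stats::uniroot(g, c(1e-2, 100))$root, error = function(e) NA)
  if (is.na(k))
    return(list(params = c(shape = NA, scale = NA), negLL = Inf,
                converged = FALSE))
  lam <- mean(x^k)^(1 / k)
  list(params = c(shape = k, scale = lam),
       negLL = -sum(stats::dweibull(x, k, lam, log = TRUE)),
       converged = TRUE)
}

fitStudentsTML <- function(x) {
  m0 <- stats::median(x)
  s0 <- max(stats::IQR(x) / 1.349, 1e-6)
  start <- c(m0, log(s0), log(6))
  nll <- function(p) {
    v <- -sum(dlst(x, p[1], exp(p[2]), exp(p[3]), log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  conv <- opt$convergence == 0
  list(params = c(location = opt$par[1], scale = exp(opt$par[2]),
                  df = exp(opt$par[3])),
       negLL = opt$value, converged = conv)
}

.familyFitters <- list(
  Weibull = list(fit = fitWeibullML, positive = TRUE),
  Gaussian = list(fit = fitGaussianML, positive = FALSE),
  Gamma = list(fit = fitGammaML, positive = TRUE),
  InverseGamma = list(fit = fitInvGammaML, positive = TRUE),
  StudentsT = list(fit = fitStudentsTML, positive = FALSE),
  Exponential = list(fit = fitExponentialML, positive = TRUE),
  LogNormal = list(fit = fitLogNormalML, positive = TRUE),
  Laplace = list(fit = fitLaplaceML, positive = FALSE),
  Rayleigh = list(fit = fitRayleighML, positive = TRUE))

#' Rank nine distribution families by maximum-likelihood fit
#'
#' Fits Weibull, Gaussian, Gamma, inverse-gamma, (three-parameter)
#' Student's-t, exponential, log-normal, Laplace and Rayleigh distributions
#' to a sample by maximum likelihood and ranks the families by attained
#' negative log-likelihood (rank 1 = smallest). Positive-support families
#' are skipped (flagged non-converged) when the sample contains
#' non-positive values; non-converged fits are excluded from the ranking.
#' The procedure is deterministic for a given sample.
#'
#' @param samples numeric vector, at least 30 finite values.
#' @param families character subset of the nine family names (default
#'   all).
#' @return A data.frame with columns `family`, `negLL`, `rank`,
#'   `converged` and a `params` list-column of fitted parameter vectors,
#'   ordered by rank.
#' @examples
#' set.seed(1)
#' r <- rankDistributions(rinvgamma(2000, 3, 2))
#' r$family[1] # "InverseGamma"
#' @export
rankDistributions <- function(samples,
                              families = names(.familyFitters)) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30)
    stop("at least 30 finite samples are required")
  if (stats::var(samples) < 1e-12)
    stop("samples are near-degenerate (variance below tolerance)")
  families <- match.arg(families, names(.familyFitters),
                        several.ok = TRUE)
  allPositive <- all(samples > 0)
  res <- lapply(families, function(f) {
    spec <- .familyFitters[[f]]
    if (spec$positive && !allPositive)
      return(list(params = NULL, negLL = Inf, converged = FALSE))
    tryCatch(spec$fit(samples),
             error = function(e)
               list(params = NULL, negLL = Inf, converged = FALSE))
  })
  negLL <- vapply(res, function(r)
    if (isTRUE(r$converged)) r$negLL else Inf, 0)
  converged <- vapply(res, function(r)
    isTRUE(r$converged) && is.finite(r$negLL), TRUE)
  rank <- rep(NA_integer_, length(families))
  rank[converged] <- base::rank(negLL[converged], ties.method = "first")
  out <- data.frame(family = families, negLL = negLL, rank = rank,
                    converged = converged, stringsAsFactors = FALSE)
  out$params <- lapply(res, `[[`, "params")
  out[order(out$rank, na.last = TRUE), , drop = FALSE]
}

#' Fit a three-parameter Student's-t distribution
#'
#' Maximum-likelihood fit of a location-scale Student's-t (location,
#' scale, degrees of freedom) by numerical optimization from moment-based
#' start values. Under the slice-power model the voxel-intensity marginal
#' is exactly of this family with degrees of freedom twice the
#' inverse-gamma shape.
#'
#' @param samples numeric vector, at least 50 values.
#' @return A list with `params` (a [GeneralizedTParams-class]), `negLL`
#'   and `converged`; non-convergence is flagged, never silently replaced.
#' @export
fitGeneralizedT <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 50)
    stop("at least 50 finite samples are required")
  fit <- fitStudentsTML(samples)
  params <- if (fit$converged)
    new("GeneralizedTParams", location = unname(fit$params["location"]),
        dof = unname(fit$params["df"]),
        scaleSq = unname(fit$params["scale"])^2)
  else NULL
  list(params = params, negLL = fit$negLL, converged = fit$converged)
}

#' Pairwise Wilcoxon tests of slice-variance distributions
#'
#' Tests, for every pair of slices, whether the two slice-variance series
#' are drawn from distributions with equal location. The default is the
#' signed-rank test on time-paired differences (slice-variance series
#' share time indices); the unpaired rank-sum variant is available via
#' `paired = FALSE`. P-values use the normal approximation with
#' continuity correction. Matrix entry TRUE means the null of equal
#' location was rejected at `alpha`: the two slices' variance processes
#' are judged dissimilar.
#'
#' @param sliceVars list of at least two [SliceVarianceSeries-class] with
#'   equal length.
#' @param alpha significance level (default 0.01).
#' @param paired use the signed-rank test on paired differences (default
#'   TRUE) or the rank-sum test (FALSE).
#' @return A symmetric logical matrix with FALSE diagonal; attribute
#'   `"p.values"` carries the p-value matrix, and attribute
#'   `"degenerate"` any all-zero-difference pairs (reported not-rejected
#'   with a warning).
#' @export
pairwiseSliceTests <- function(sliceVars, alpha = 0.01, paired = TRUE) {
  ns <- length(sliceVars)
  if (ns < 2) stop("at least 2 slices are required")
  Tlens <- vapply(sliceVars, function(s) length(s@values), 0L)
  if (paired && length(unique(Tlens)) != 1L)
    stop("paired testing requires equal series length across slices")
  labels <- vapply(sliceVars, function(s) s@slice, 0L)
  dec <- matrix(FALSE, ns, ns, dimnames = list(labels, labels))
  pmat <- matrix(NA_real_, ns, ns, dimnames = list(labels, labels))
  degenerate <- character()
  for (i in seq_len(ns)) {
    pmat[i, i] <- 1
    for (j in seq_len(ns)[-seq_len(i)]) {
      a <- sliceVars[[i]]@values; b <- sliceVars[[j]]@values
      if (paired && all(a == b)) {
        degenerate <- c(degenerate, sprintf("%d-%d", labels[i], labels[j]))
        p <- 1
      } else {
        p <- suppressWarnings(stats::wilcox.test(
          a, b, paired = paired, exact = FALSE, correct = TRUE,
          alternative = "two.sided")$p.value)
      }
      pmat[i, j] <- pmat[j, i] <- p
      dec[i, j] <- dec[j, i] <- p < alpha
    }
  }
  if (length(degenerate))
    warning("degenerate (all-zero-difference) slice pairs: ",
            paste(degenerate, collapse = ", "))
  attr(dec, "p.values") <- pmat
  attr(dec, "degenerate") <- degenerate
  dec
}
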