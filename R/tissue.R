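#' @include AllClasses.R statfit.R correction.R
NULL

residualize <- function(y, x) {
  stats::lm.fit(cbind(1, x), y)$residuals
}

# Pearson correlation that returns NA (instead of warning) for a
# zero-variance argument, e.g. a tissue whose proportion is identical in
# every slice
safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Association between tissue-type variance and slice variance
#'
#' Determines whether tissue composition drives the slice-dependent
#' time-varying variance. Three steps: (i) for every tissue label, the
#' cross-sectional variance over that tissue's voxels (whole volume) is
#' computed at each time point; (ii) the whole-volume variance series —
#' shared by construction between tissue and slice estimates — is
#' regressed out of both the tissue series and every slice-variance
#' series; (iii) residual-residual Pearson correlations are tested per
#' (slice, tissue) with a Student's-t test, and per-slice inverse-gamma
#' parameter estimates (MLE on the slice-variance values) are correlated
#' across slices with per-slice tissue proportions and tested with
#' Fisher's z.
#'
#' @param volume a [BoldVolume-class].
#' @param tissueLabels 3D integer array of tissue labels (0 = background)
#'   aligned with the volume.
#' @param sliceVars list of [SliceVarianceSeries-class] for the volume
#'   (e.g. from [estimateSliceVariance()]).
#' @param alpha significance level (default 0.01).
#' @return A list with `sliceTissue` (data.frame: slice, tissue,
#'   correlation of residual series, t statistic, p value, significant),
#'   `igTissue` (data.frame: tissue, parameter (shape/scale), correlation
#'   with tissue proportion across slices, Fisher z, p value,
#'   significant), `tissueVariance` (T-by-nTissue matrix of tissue
#'   variance series) and `wholeVolumeVariance`.
#' @export
tissueVarianceAssociation <- function(volume, tissueLabels, sliceVars,
                                      alpha = 0.01) {
  stopifnot(is(volume, "BoldVolume"))
  d <- dim(volume@data)
  if (!identical(dim(tissueLabels), d[1:3]))
    stop("'tissueLabels' must align with the volume's spatial grid")
  labs <- sort(unique(as.integer(tissueLabels[tissueLabels > 0])))
  if (length(labs) < 2) stop("at least 2 tissue labels are required")
  T <- d[4]
  mat <- matrix(volume@data, ncol = T)
  labVec <- as.integer(tissueLabels)

  tissueVar <- sapply(labs, function(l) {
    vox <- which(labVec == l)
    if (!length(vox)) stop(sprintf("tissue label %d has an empty mask", l))
    crossSectionalVar(mat[vox, , drop = FALSE])
  })
  colnames(tissueVar) <- paste0("tissue", labs)
  wholeVar <- crossSectionalVar(mat[labVec > 0, , drop = FALSE])

  tissueRes <- apply(tissueVar, 2, residualize, x = wholeVar)
  sliceRes <- sapply(sliceVars, function(s) residualize(s@values, wholeVar))
  sliceIdx <- vapply(sliceVars, function(s) s@slice, 0L)

  st <- expand.grid(slice = sliceIdx, tissue = labs)
  st$correlation <- mapply(function(si, ti)
    safeCor(sliceRes[, which(sliceIdx == si)],
            tissueRes[, which(labs == ti)]),
    st$slice, st$tissue)
  st$t <- st$correlation * sqrt((T - 2) / (1 - st$correlation^2))
  st$p <- 2 * stats::pt(-abs(st$t), df = T - 2)
  st$significant <- !is.na(st$p) & st$p < alpha

  # per-slice inverse-gamma MLE vs per-slice tissue proportions
  igFit <- t(vapply(sliceVars, function(s) {
    f <- fitInvGammaML(s@values)
    c(shape = unname(f$params["shape"]), scale = unname(f$params["scale"]))
  }, c(shape = 0, scale = 0)))
  ax <- volume@sliceAxis
  nz <- d[ax]
  prop <- sapply(labs, function(l) {
    vapply(seq_len(nz), function(z) {
      sel <- switch(ax, labVec[slice.index(tissueLabels, 1) == z],
                    labVec[slice.index(tissueLabels, 2) == z],
                    labVec[slice.index(tissueLabels, 3) == z])
      mean(sel == l)
    }, 0)
  })
  nzUsed <- length(sliceVars)
  propUsed <- prop[match(sliceIdx, seq_len(nz) - 1L), , drop = FALSE]
  ig <- expand.grid(tissue = labs, parameter = c("shape", "scale"),
                    stringsAsFactors = FALSE)
  ig$correlation <- mapply(function(ti, pa)
    safeCor(igFit[, pa], propUsed[, which(labs == ti)]),
    ig$tissue, ig$parameter)
  ig$z <- atanh(pmin(pmax(ig$correlation, -1 + 1e-15), 1 - 1e-15)) *
    sqrt(max(nzUsed - 3, 1))
  ig$p <- 2 * stats::pnorm(-abs(ig$z))
  ig$significant <- !is.na(ig$p) & ig$p < alpha

  list(sliceTissue = st, igTissue = ig, tissueVariance = tissueVar,
       wholeVolumeVariance = wholeVar)
}
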