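#' @include AllClasses.R
NULL

#' Mean timeseries of a seed region
#'
#' Unweighted voxel-mean series over a region-of-interest mask.
#'
#' @param volume a [BoldVolume-class].
#' @param roiMask 3D logical array selecting the seed voxels; must be
#'   non-empty and, when the volume carries a brain mask, contained in it.
#' @return Numeric series of length T.
#' @export
seedTimeseries <- function(volume, roiMask) {
  stopifnot(is(volume, "BoldVolume"))
  d <- dim(volume@data)
  if (!identical(dim(roiMask), d[1:3]))
    stop("'roiMask' must align with the volume's spatial grid")
  sel <- which(as.logical(roiMask))
  if (!length(sel)) stop("the seed ROI is empty")
  if (!is.null(volume@brainMask) &&
      any(!as.logical(volume@brainMask)[sel]))
    stop("the seed ROI extends outside the brain mask")
  mat <- matrix(volume@data, ncol = d[4])
  colMeans(mat[sel, , drop = FALSE])
}

#' Seed-voxel Pearson correlation map
#'
#' Per-voxel Pearson correlation (mean-removed, normalized) of every
#' in-mask voxel series with the seed series. Zero-variance voxel series
#' have undefined correlation; they are dropped (NA in the map) and their
#' count reported in a warning and in the `"nDropped"` attribute.
#'
#' @param volume a [BoldVolume-class].
#' @param seed numeric series of length T (e.g. from [seedTimeseries()]).
#' @param mask optional 3D logical analysis mask; defaults to the
#'   volume's brain mask, or the whole grid.
#' @return 3D array of correlations, NA outside the mask; attribute
#'   `"nDropped"` counts dropped zero-variance voxels.
#' @export
correlationMap <- function(volume, seed, mask = NULL) {
  stopifnot(is(volume, "BoldVolume"))
  d <- dim(volume@data)
  T <- d[4]
  if (length(seed) != T) stop("seed length must match the volume's T")
  if (T < 4) stop("at least 4 time points are required")
  if (is.null(mask)) mask <- volume@brainMask
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3]))
    stop("'mask' must align with the volume's spatial grid")
  sel <- which(as.logical(mask))
  mat <- matrix(volume@data, ncol = T)[sel, , drop = FALSE]
  mc <- mat - rowMeans(mat)
  ss <- rowSums(mc^2)
  sc <- seed - mean(seed)
  denom <- sqrt(ss * sum(sc^2))
  r <- as.numeric(mc %*% sc) / denom
  dropped <- !is.finite(r) | ss <= 0
  nDropped <- sum(dropped)
  if (nDropped)
    warning(sprintf("%d zero-variance voxel(s) dropped from the map",
                    nDropped))
  r[dropped] <- NA_real_
  out <- array(NA_real_, d[1:3])
  out[sel] <- r
  attr(out, "nDropped") <- as.integer(nDropped)
  out
}

#' Fisher-z significance thresholding of a correlation map
#'
#' Transforms the map with Fisher's z (`atanh`), standardizes by
#' `sqrt(df - 3)` and applies a two-sided Bonferroni-corrected threshold
#' at `alpha / nTests`, where `nTests` counts the in-map (non-NA) voxels.
#' The default degrees of freedom is the series length T; a corrected
#' effective df accounting for sample dependence can be supplied through
#' `effectiveDf` (a number, or a function of the r map returning one).
#' Saturated voxels (|r| = 1, infinite z) are reported significant and
#' counted in `@nSaturated`.
#'
#' @param rmap 3D correlation array from [correlationMap()].
#' @param T series length the correlations were computed from.
#' @param alpha significance level before correction (default 0.01).
#' @param correction multiplicity correction; only `"bonferroni"`.
#' @param effectiveDf effective degrees of freedom hook: NULL (use T), a
#'   single number, or `function(rmap) -> number`. Must exceed 3.
#' @return A [ConnectivityMap-class].
#' @examples
#' r <- array(c(0, 0.3, NA), c(3, 1, 1))
#' m <- fisherZThreshold(r, T = 219)
#' m@threshold
#' @export
fisherZThreshold <- function(rmap, T, alpha = 0.01,
                             correction = "bonferroni",
                             effectiveDf = NULL) {
  correction <- match.arg(correction)
  df <- if (is.null(effectiveDf)) T
        else if (is.function(effectiveDf)) effectiveDf(rmap)
        else effectiveDf
  if (df <= 3) stop("effective degrees of freedom must exceed 3")
  nTests <- sum(!is.na(rmap))
  if (nTests < 1) stop("the map contains no testable voxels")
  z <- atanh(rmap)
  stat <- z * sqrt(df - 3)
  thr <- stats::qnorm(1 - alpha / (2 * nTests))
  saturated <- is.infinite(z) & !is.na(z)
  sig <- (abs(stat) > thr) | saturated
  sig[is.na(sig)] <- FALSE
  new("ConnectivityMap",
      rMap = array(as.numeric(rmap), dim(rmap)), zMap = z,
      sigMask = sig, alpha = alpha, nTests = as.integer(nTests),
      effectiveDf = as.numeric(df), threshold = thr,
      nSaturated = as.integer(sum(saturated)),
      nDropped = as.integer(attr(rmap, "nDropped") %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
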