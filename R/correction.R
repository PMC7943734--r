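#' @include AllClasses.R AllGenerics.R
NULL

newSliceVarianceSeries <- function(slice, values, nVoxels) {
  new("SliceVarianceSeries", slice = as.integer(slice),
      values = as.numeric(values), nVoxels = as.integer(nVoxels),
      estimator = "unbiased")
}

# unbiased cross-sectional variance of a voxels-by-time matrix, per column
crossSectionalVar <- function(mat) {
  n <- nrow(mat)
  mu <- colMeans(mat)
  (colSums(mat^2) - n * mu^2) / (n - 1)
}

#' @describeIn estimateSliceVariance per slice of the slice axis, the
#'   unbiased variance over in-mask voxels at each time point (set
#'   `useMask = FALSE` to include background voxels).
#' @export
setMethod("estimateSliceVariance", "BoldVolume",
function(x, useMask = TRUE) {
  d <- dim(x@data)
  ax <- x@sliceAxis
  nz <- d[ax]
  mask <- if (useMask && !is.null(x@brainMask)) x@brainMask else
    array(TRUE, d[1:3])
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    sel <- switch(ax,
      as.logical(mask[z, , ]),
      as.logical(mask[, z, ]),
      as.logical(mask[, , z]))
    slab <- switch(ax,
      x@data[z, , , , drop = FALSE],
      x@data[, z, , , drop = FALSE],
      x@data[, , z, , drop = FALSE])
    slab <- matrix(slab, ncol = d[4])[sel, , drop = FALSE]
    if (nrow(slab) < 2L)
      stop(sprintf("slice %d has fewer than 2 in-mask voxels", z - 1L))
    out[[z]] <- newSliceVarianceSeries(z - 1L, crossSectionalVar(slab),
                                       nrow(slab))
  }
  out
})

#' @describeIn estimateSliceVariance variance across all x series (slice
#'   m) and all y series (slice n) of the dataset at each time point.
#' @export
setMethod("estimateSliceVariance", "PairDataset",
function(x) {
  if (ncol(x@x) < 2L)
    stop("at least 2 series per slice are required")
  list(newSliceVarianceSeries(x@sliceX, crossSectionalVar(t(x@x)),
                              ncol(x@x)),
       newSliceVarianceSeries(x@sliceY, crossSectionalVar(t(x@y)),
                              ncol(x@y)))
})

checkVarianceFloor <- function(sv, floor) {
  bad <- which(sv@values <= floor)
  if (length(bad))
    stop(sprintf(
      "slice %d variance is at or below the floor (%g) at %d time point(s); refusing to correct",
      sv@slice, floor, length(bad)))
}

#' @describeIn precisionCorrect every in-mask voxel sample of slice m at
#'   time t is divided by `sqrt(sliceVars[[m]]@values[t])`. The raw signal,
#'   including its mean, is divided; means are deliberately not re-centred
#'   first, so signal means change by the same per-slice factor.
#' @export
setMethod("precisionCorrect", "BoldVolume",
function(x, sliceVars, floor = 1e-12) {
  d <- dim(x@data)
  ax <- x@sliceAxis
  nz <- d[ax]
  bySlice <- stats::setNames(sliceVars,
                             vapply(sliceVars, function(s) s@slice, 0L))
  out <- x@data
  for (z in seq_len(nz)) {
    sv <- bySlice[[as.character(z - 1L)]]
    if (is.null(sv))
      stop(sprintf("no slice-variance series supplied for slice %d",
                   z - 1L))
    if (length(sv@values) != d[4])
      stop("slice-variance series length does not match T")
    checkVarianceFloor(sv, floor)
    w <- 1 / sqrt(sv@values)
    wfull <- rep(w, each = prod(d[1:3]) / nz)
    switch(ax,
      out[z, , , ] <- out[z, , , ] * array(wfull, c(d[2], d[3], d[4])),
      out[, z, , ] <- out[, z, , ] * array(wfull, c(d[1], d[3], d[4])),
      out[, , z, ] <- out[, , z, ] * array(wfull, c(d[1], d[2], d[4])))
  }
  BoldVolume(out, sliceAxis = ax, brainMask = x@brainMask,
             header = x@header)
})

#' @describeIn precisionCorrect divides all x series by the slice-m
#'   estimate and all y series by the slice-n estimate; the result is at
#'   stage `"corrected"`.
#' @export
setMethod("precisionCorrect", "PairDataset",
function(x, sliceVars, floor = 1e-12) {
  bySlice <- stats::setNames(sliceVars,
                             vapply(sliceVars, function(s) s@slice, 0L))
  svX <- bySlice[[as.character(x@sliceX)]]
  svY <- bySlice[[as.character(x@sliceY)]]
  if (is.null(svX) || is.null(svY))
    stop("slice-variance series must cover both slices of the dataset")
  T <- nrow(x@x)
  if (length(svX@values) != T || length(svY@values) != T)
    stop("slice-variance series length does not match T")
  checkVarianceFloor(svX, floor)
  checkVarianceFloor(svY, floor)
  new("PairDataset",
      x = x@x / sqrt(svX@values), y = x@y / sqrt(svY@values),
      sliceX = x@sliceX, sliceY = x@sliceY, stage = "corrected",
      stationaryX = x@stationaryX, stationaryY = x@stationaryY,
      powerX = x@powerX, powerY = x@powerY,
      groundTruth = x@groundTruth)
})

#' Slice-variance series as true power processes
#'
#' Wraps known (oracle) power series as [SliceVarianceSeries-class]
#' objects so [precisionCorrect()] can be run against the true
#' time-varying power instead of an estimate.
#'
#' @param ds a weighted [PairDataset-class] carrying realized power
#'   series.
#' @return A list of two [SliceVarianceSeries-class].
#' @export
oracleSliceVariance <- function(ds) {
  stopifnot(is(ds, "PairDataset"))
  if (is.null(ds@powerX) || is.null(ds@powerY))
    stop("dataset carries no realized power series")
  list(newSliceVarianceSeries(ds@sliceX, ds@powerX, ncol(ds@x)),
       newSliceVarianceSeries(ds@sliceY, ds@powerY, ncol(ds@y)))
}

#' Tidy per-slice variance table
#'
#' @param sliceVars list of [SliceVarianceSeries-class].
#' @return A data.frame with columns `slice` (0-based), `t` (0-based),
#'   `variance`, `n_voxels`.
#' @export
sliceVarianceTable <- function(sliceVars) {
  do.call(rbind, lapply(sliceVars, function(s)
    data.frame(slice = s@slice, t = seq_along(s@values) - 1L,
               variance = s@values, n_voxels = s@nVoxels)))
}
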