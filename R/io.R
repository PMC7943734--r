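#' @include AllClasses.R connectivity.R correction.R
NULL

#' Read a 4D NIfTI volume (and optional mask) as a BoldVolume
#'
#' Loads a NIfTI-1/2 file with intensity scaling (scl slope/intercept)
#' applied per the NIfTI standard, retaining the header for write-back.
#'
#' @param path path to a 4D NIfTI file.
#' @param maskPath optional path to a 3D binary mask NIfTI whose spatial
#'   shape must match the volume.
#' @param sliceAxis spatial axis indexing acquisition slices (default 3).
#' @return A [BoldVolume-class].
#' @export
readBoldVolume <- function(path, maskPath = NULL, sliceAxis = 3L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is %dD; a 4D volume is required", path, length(d)))
  mask <- NULL
  if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    if (!identical(dim(m)[1:3], d[1:3]))
      stop("mask shape does not match the volume's spatial grid")
    mask <- array(as.array(m) != 0, d[1:3])
  }
  BoldVolume(array(as.numeric(img), d), sliceAxis = sliceAxis,
             brainMask = mask, header = RNifti::niftiHeader(img))
}

#' Write a BoldVolume (or a 3D map) as NIfTI
#'
#' The input volume's header/affine is reused when present so output maps
#' share the input spatial metadata.
#'
#' @param x a [BoldVolume-class] or a numeric array.
#' @param path output file path (`.nii` / `.nii.gz`).
#' @param reference optional [BoldVolume-class] supplying header metadata
#'   when `x` is a bare array.
#' @return The path, invisibly.
#' @export
writeBoldVolume <- function(x, path, reference = NULL) {
  if (is(x, "BoldVolume")) {
    arr <- x@data
    hdr <- x@header
  } else {
    arr <- x
    hdr <- if (!is.null(reference)) reference@header else NULL
  }
  img <- if (!is.null(hdr)) RNifti::asNifti(arr, reference = hdr)
         else RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write connectivity-map outputs
#'
#' Writes the r map, z map and binary significance mask as NIfTI files
#' plus a JSON summary (number significant, threshold, df, alpha,
#' nTests).
#'
#' @param map a [ConnectivityMap-class].
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param reference optional [BoldVolume-class] supplying the affine.
#' @param overwrite allow replacing existing files (default FALSE).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeConnectivityMap <- function(map, outDir, prefix = "seedmap",
                                 reference = NULL, overwrite = FALSE) {
  stopifnot(is(map, "ConnectivityMap"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(r = file.path(outDir, paste0(prefix, "_r.nii.gz")),
             z = file.path(outDir, paste0(prefix, "_z.nii.gz")),
             sig = file.path(outDir, paste0(prefix, "_sig.nii.gz")),
             summary = file.path(outDir, paste0(prefix, "_summary.json")))
  if (!overwrite && any(file.exists(paths)))
    stop("output files exist; set overwrite = TRUE to replace them")
  writeBoldVolume(map@rMap, paths["r"], reference = reference)
  z <- map@zMap
  z[is.infinite(z)] <- sign(z[is.infinite(z)]) * .Machine$double.xmax
  writeBoldVolume(z, paths["z"], reference = reference)
  writeBoldVolume(array(as.numeric(map@sigMask), dim(map@sigMask)),
                  paths["sig"], reference = reference)
  jsonlite::write_json(
    list(nSignificant = sum(map@sigMask), threshold = map@threshold,
         effectiveDf = map@effectiveDf, alpha = map@alpha,
         nTests = map@nTests, nSaturated = map@nSaturated,
         nDropped = map@nDropped),
    paths["summary"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a per-slice variance table as CSV
#'
#' Columns: `slice` (0-based), `t` (0-based), `variance`, `n_voxels`.
#'
#' @param sliceVars list of [SliceVarianceSeries-class].
#' @param path output CSV path.
#' @param overwrite allow replacing an existing file.
#' @return The path, invisibly.
#' @export
writeSliceVariance <- function(sliceVars, path, overwrite = FALSE) {
  if (!overwrite && file.exists(path))
    stop("output file exists; set overwrite = TRUE to replace it")
  utils::write.csv(sliceVarianceTable(sliceVars), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-slice variance table written by [writeSliceVariance()]
#'
#' @param path CSV path.
#' @return A list of [SliceVarianceSeries-class].
#' @export
readSliceVariance <- function(path) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$slice), function(d)
    newSliceVarianceSeries(d$slice[1], d$variance[order(d$t)],
                           d$n_voxels[1]))
}
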