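#' @include AllClasses.R simulate.R
NULL

#' Generate a synthetic 4D BOLD volume with slice-dependent power
#'
#' Builds a 4D volume whose voxel timeseries are
#' (tissue baseline + ROI-correlated latent signal + white noise)
#' multiplied at each time point by the square root of a slice-specific
#' inverse-gamma power process. The generator records the full ground
#' truth (realized slice power, latent signals, target ROI correlations,
#' tissue labels) so slice-variance estimation, distribution ranking,
#' correction and connectivity mapping can be validated against it.
#'
#' ROI latent signals are unit-variance Gaussian series with correlation
#' matrix `roiCor`; voxels inside ROI k receive `signalSd * latent_k` plus
#' iid `N(0, noiseSd^2)` noise, voxels outside any ROI receive noise only.
#' Tissue labels (integer array, 0 = background) shift the baseline mean
#' via `baselineMeans`, making tissue masks non-trivial.
#'
#' @param dims integer vector (nx, ny, nz, T).
#' @param slicePowerSpecs list of `nz` [PowerProcessSpec-class] objects,
#'   one per slice of the third axis, or NULL for constant unit power.
#' @param roiMasks list of 3D logical arrays, pairwise disjoint.
#' @param roiCor K-by-K correlation matrix of the ROI latent signals.
#' @param tissueLabels optional 3D integer array of tissue labels
#'   (0 = background); defaults to a single tissue covering the volume.
#' @param baselineMeans numeric vector of baseline intensities, one per
#'   positive tissue label.
#' @param signalSd,noiseSd standard deviations of the ROI latent signal
#'   contribution and of the voxelwise white noise.
#' @param seed optional integer seed.
#' @return A list with elements `volume` (a [BoldVolume-class], brain mask
#'   = tissue > 0), `power` (nz-by-T matrix of realized slice power),
#'   `latent` (T-by-K matrix), `roiMasks`, `roiCor`, `tissueLabels` and
#'   `specs`.
#' @export
generateSyntheticBold <- function(dims, slicePowerSpecs = NULL,
                                  roiMasks = list(), roiCor = NULL,
                                  tissueLabels = NULL,
                                  baselineMeans = 100,
                                  signalSd = 1, noiseSd = 1,
                                  seed = NULL) {
  if (length(dims) != 4L) stop("'dims' must be (nx, ny, nz, T)")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]; T <- dims[4]
  if (!is.null(slicePowerSpecs) && length(slicePowerSpecs) != nz)
    stop("need one power specification per slice (dimension mismatch)")
  K <- length(roiMasks)
  if (K > 1) {
    overlap <- Reduce(`+`, lapply(roiMasks, function(m) m + 0))
    if (any(overlap > 1)) stop("ROI masks must be pairwise disjoint")
  }
  if (K > 0) {
    if (is.null(roiCor)) roiCor <- diag(K)
    if (!all(dim(roiCor) == c(K, K)))
      stop("'roiCor' must be K x K for K ROIs")
    offDiag <- roiCor[upper.tri(roiCor)]
    if (length(offDiag) && any(abs(offDiag) >= 1))
      stop("target ROI correlations must lie in (-1, 1)")
  }
  if (is.null(tissueLabels)) {
    tissueLabels <- array(1L, dims[1:3])
  } else if (!identical(dim(tissueLabels), as.integer(dims[1:3]))) {
    stop("'tissueLabels' shape must match the spatial grid")
  }
  nTissue <- max(tissueLabels)
  if (length(baselineMeans) == 1L)
    baselineMeans <- rep(baselineMeans, max(nTissue, 1L))
  if (nTissue > length(baselineMeans))
    stop("need one baseline mean per tissue label")
  if (!is.null(seed)) set.seed(seed)

  # latent ROI signals with target correlation matrix
  latent <- NULL
  if (K > 0) {
    L <- chol(roiCor)
    latent <- matrix(stats::rnorm(T * K), T, K) %*% L
  }

  nvox <- nx * ny * nz
  baseline <- numeric(nvox)
  lab <- as.integer(tissueLabels)
  baseline[lab > 0] <- baselineMeans[lab[lab > 0]]

  # voxels x time stationary component
  mat <- matrix(stats::rnorm(nvox * T, sd = noiseSd), nvox, T)
  mat <- mat + baseline
  if (K > 0) {
    for (k in seq_len(K)) {
      vk <- which(as.logical(roiMasks[[k]]))
      if (length(vk))
        mat[vk, ] <- mat[vk, ] +
          matrix(signalSd * latent[, k], length(vk), T, byrow = TRUE)
    }
  }

  power <- matrix(1, nz, T)
  if (!is.null(slicePowerSpecs)) {
    for (z in seq_len(nz))
      power[z, ] <- samplePowerProcess(slicePowerSpecs[[z]], T)
  }
  sliceOf <- rep(seq_len(nz), each = nx * ny)
  mat <- mat * sqrt(power[sliceOf, , drop = FALSE])

  vol <- BoldVolume(array(mat, c(nx, ny, nz, T)), sliceAxis = 3L,
                    brainMask = array(tissueLabels > 0, dims[1:3]))
  list(volume = vol, power = power, latent = latent, roiMasks = roiMasks,
       roiCor = roiCor, tissueLabels = tissueLabels,
       specs = slicePowerSpecs)
}
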