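# shared helpers for the slicevar test suite

# slope of the first principal axis of an (x, y) scatter
principalAxisSlope <- function(x, y) {
  v <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
  v[2] / v[1]
}

# delta-method standard error of the time-averaged kappa estimator for one
# realized weight-series pair: accounts for the fact that all pairs of a
# dataset share a single power realization per slice
kappaHatSE <- function(powerX, powerY) {
  w <- sqrt(powerX); v <- sqrt(powerY)
  A <- mean(w * v); B <- mean(w^2); C <- mean(v^2)
  k <- A / sqrt(B * C)
  g <- (w * v - A) / sqrt(B * C) - k * (w^2 - B) / (2 * B) -
    k * (v^2 - C) / (2 * C)
  stats::sd(g) / sqrt(length(g))
}

# tiny all-foreground BoldVolume filled with iid noise
makeNoiseVolume <- function(dims, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  BoldVolume(array(stats::rnorm(prod(dims), sd = sd), dims),
             brainMask = array(TRUE, dims[1:3]))
}
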