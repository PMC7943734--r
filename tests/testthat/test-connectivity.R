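test_that("seed timeseries is the unweighted ROI mean", {
  vol <- makeNoiseVolume(c(4, 4, 2, 30), seed = 61)
  roi1 <- array(FALSE, c(4, 4, 2)); roi1[2, 3, 1] <- TRUE
  expect_equal(seedTimeseries(vol, roi1), boldData(vol)[2, 3, 1, ])

  dup <- boldData(vol); dup[1, 1, 1, ] <- dup[2, 2, 1, ]
  vol2 <- BoldVolume(dup)
  roi2 <- array(FALSE, c(4, 4, 2)); roi2[1, 1, 1] <- roi2[2, 2, 1] <- TRUE
  expect_equal(seedTimeseries(vol2, roi2), dup[1, 1, 1, ])

  expect_error(seedTimeseries(vol, array(FALSE, c(4, 4, 2))), "empty")
  bm <- array(TRUE, c(4, 4, 2)); bm[2, 3, 1] <- FALSE
  vol3 <- BoldVolume(boldData(vol), brainMask = bm)
  expect_error(seedTimeseries(vol3, roi1), "outside")
})

test_that("ROI averaging suppresses voxel noise in the seed", {
  set.seed(62)
  T <- 120; common <- rnorm(T)
  dat <- array(rnorm(6 * 6 * 1 * T, sd = 2), c(6, 6, 1, T))
  dat <- dat + rep(common, each = 36)
  vol <- BoldVolume(dat)
  roiSmall <- array(FALSE, c(6, 6, 1)); roiSmall[1, 1, 1] <- TRUE
  roiBig <- array(FALSE, c(6, 6, 1)); roiBig[1:4, 1:4, 1] <- TRUE
  expect_gt(cor(seedTimeseries(vol, roiBig), common),
            cor(seedTimeseries(vol, roiSmall), common))
})

test_that("correlation maps hit the exact cases and drop dead voxels", {
  vol <- makeNoiseVolume(c(3, 3, 1, 50), seed = 63)
  dat <- boldData(vol)
  seed <- dat[1, 1, 1, ]
  dat[2, 2, 1, ] <- -seed
  dat[3, 3, 1, ] <- 7 # constant voxel
  vol <- BoldVolume(dat)
  expect_warning(r <- correlationMap(vol, seed), "zero-variance")
  expect_equal(r[1, 1, 1], 1)
  expect_equal(r[2, 2, 1], -1)
  expect_true(is.na(r[3, 3, 1]))
  expect_identical(attr(r, "nDropped"), 1L)
  expect_error(correlationMap(vol, seed[1:10]), "length")
})

test_that("planted seed-target correlation is attenuated then restored", {
  specs <- list(PowerProcessSpec(2, 2), PowerProcessSpec(3, 2))
  kap <- kappaTheoretical(specs[[1]], specs[[2]])
  roiSeed <- array(FALSE, c(16, 16, 2)); roiSeed[4:6, 4:6, 1] <- TRUE
  roiTarg <- array(FALSE, c(16, 16, 2)); roiTarg[10:12, 10:12, 2] <- TRUE
  rhoTrue <- 0.5
  # voxel-level truth: latent-signal share on both the voxel and the
  # 9-voxel seed average (signalSd = 2, noiseSd = 1)
  rVoxel <- 4 * rhoTrue / (sqrt(4 + 1) * sqrt(4 + 1 / 9))
  set.seed(64)
  pre <- post <- numeric(25)
  for (i in 1:25) {
    g <- generateSyntheticBold(c(16, 16, 2, 200), specs,
                               list(roiSeed, roiTarg),
                               roiCor = matrix(c(1, rhoTrue, rhoTrue, 1), 2),
                               baselineMeans = 0, signalSd = 2,
                               noiseSd = 1)
    sm <- correlationMap(g$volume, seedTimeseries(g$volume, roiSeed))
    pre[i] <- mean(sm[roiTarg])
    cv <- precisionCorrect(g$volume, estimateSliceVariance(g$volume))
    cm <- correlationMap(cv, seedTimeseries(cv, roiSeed))
    post[i] <- mean(cm[roiTarg])
  }
  # uncorrected: attenuated toward kappa * rVoxel; corrected: near rVoxel
  expect_lt(abs(mean(pre) - kap * rVoxel), 3 * sd(pre) / 5 + 0.03)
  expect_lt(abs(mean(post) - rVoxel), 3 * sd(post) / 5 + 0.03)
  expect_gt(mean(post), mean(pre))
})

test_that("Fisher-z thresholding standardizes and corrects as stated", {
  r <- array(c(0, 0.3, 0.9999999, NA), c(4, 1, 1))
  m <- fisherZThreshold(r, T = 219, alpha = 0.01)
  expect_equal(zMap(m)[2, 1, 1] * sqrt(219 - 3), 4.549, tolerance = 1e-3)
  expect_identical(m@nTests, 3L)
  expect_equal(m@threshold, qnorm(1 - 0.01 / (2 * 3)))
  expect_false(sigMask(m)[1, 1, 1]) # r = 0 is never significant
  expect_true(sigMask(m)[3, 1, 1])
  expect_false(sigMask(m)[4, 1, 1])

  sat <- fisherZThreshold(array(1, c(1, 1, 1)), T = 50)
  expect_identical(sat@nSaturated, 1L)
  expect_true(sigMask(sat)[1, 1, 1])

  # effective-df hook lowers the standardized statistic
  m2 <- fisherZThreshold(r, T = 219, effectiveDf = 100)
  expect_equal(zMap(m2)[2, 1, 1] * sqrt(100 - 3),
               atanh(0.3) * sqrt(97), tolerance = 1e-10)
  expect_error(fisherZThreshold(r, T = 219, effectiveDf = 3), "exceed 3")
})

test_that("correction amplifies attenuated correlation estimates", {
  # VAR pairs give a wide spread of underlying correlations, so the
  # pre/post scatter's principal axis reflects the 1/kappa amplification
  ds <- generateVarPairs(600, T = 300, meanRange = c(0, 0), seed = 65)
  w <- applyPowerWeighting(ds, PowerProcessSpec(2, 2),
                           PowerProcessSpec(3, 2), seed = 66)
  cd <- precisionCorrect(w, estimateSliceVariance(w))
  slope <- principalAxisSlope(pairCorrelations(w), pairCorrelations(cd))
  expect_gt(slope, 1)
})

test_that("pre/post contrast: corrected maps are cleaner and closer", {
  specs <- list(PowerProcessSpec(1.5, 2), PowerProcessSpec(4, 2))
  roiSeed <- array(FALSE, c(12, 12, 2)); roiSeed[3:5, 3:5, 1] <- TRUE
  roiTarg <- array(FALSE, c(12, 12, 2)); roiTarg[8:10, 8:10, 2] <- TRUE
  rhoTrue <- 0.6
  rVoxel <- 4 * rhoTrue / (sqrt(4 + 1) * sqrt(4 + 1 / 9))
  set.seed(67)
  nRep <- 20
  preErr <- postErr <- numeric(nRep)
  preOut <- postOut <- numeric(nRep)
  outside <- !(roiSeed | roiTarg)
  for (i in seq_len(nRep)) {
    g <- generateSyntheticBold(c(12, 12, 2, 200), specs,
                               list(roiSeed, roiTarg),
                               roiCor = matrix(c(1, rhoTrue, rhoTrue, 1), 2),
                               baselineMeans = 0, signalSd = 2,
                               noiseSd = 1)
    sm <- correlationMap(g$volume, seedTimeseries(g$volume, roiSeed))
    mPre <- fisherZThreshold(sm, T = 200)
    cv <- precisionCorrect(g$volume, estimateSliceVariance(g$volume))
    cm <- correlationMap(cv, seedTimeseries(cv, roiSeed))
    mPost <- fisherZThreshold(cm, T = 200)
    preErr[i] <- abs(mean(sm[roiTarg]) - rVoxel)
    postErr[i] <- abs(mean(cm[roiTarg]) - rVoxel)
    preOut[i] <- sum(sigMask(mPre)[outside])
    postOut[i] <- sum(sigMask(mPost)[outside])
  }
  expect_lt(mean(postErr), mean(preErr))
  expect_lte(mean(postOut), mean(preOut))
})
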