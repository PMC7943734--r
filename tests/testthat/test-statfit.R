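test_that("the nine-family ranking identifies generating families", {
  set.seed(41)
  x <- rinvgamma(4000, 3, 2)
  rk <- rankDistributions(x)
  expect_identical(rk$family[1], "InverseGamma")
  expect_true(all(rk$rank[rk$converged] ==
                    rank(rk$negLL[rk$converged], ties.method = "first")))
  # permutation invariance
  rk2 <- rankDistributions(sample(x))
  expect_identical(rk$family, rk2$family)
  expect_equal(rk$negLL, rk2$negLL, tolerance = 1e-8)

  # a second seed and parameter set
  set.seed(42)
  expect_identical(rankDistributions(rinvgamma(4000, 6, 9))$family[1],
                   "InverseGamma")

  expect_error(rankDistributions(rep(1, 100)), "degenerate")
  expect_error(rankDistributions(rnorm(10)), "30")
})

test_that("Gaussian data put Gaussian and its t limit at the top", {
  # the 3-parameter t nests the Gaussian (dof -> infinity), so raw negLL
  # ranking places the two families together with a negligible gap
  set.seed(43)
  rk <- rankDistributions(rnorm(4000))
  expect_true(all(c("Gaussian", "StudentsT") %in% rk$family[1:2]))
  gap <- abs(rk$negLL[rk$family == "Gaussian"] -
               rk$negLL[rk$family == "StudentsT"])
  expect_lt(gap, 2)
  tPars <- rk$params[rk$family == "StudentsT"][[1]]
  expect_gt(tPars["df"], 20)
})

test_that("voxel-intensity draws rank Student's-t above Gaussian", {
  set.seed(44)
  x <- rnorm(4000) * sqrt(rinvgamma(4000, 2, 2))
  rk <- rankDistributions(x)
  rT <- rk$rank[rk$family == "StudentsT"]
  rG <- rk$rank[rk$family == "Gaussian"]
  expect_lt(rT, rG)
})

test_that("gamma and weibull MLEs agree with fitdistrplus", {
  skip_if_not_installed("fitdistrplus")
  set.seed(45)
  x <- rgamma(3000, shape = 2.5, rate = 0.8)
  rk <- rankDistributions(x, families = c("Gamma", "Weibull"))
  fg <- fitdistrplus::fitdist(x, "gamma")
  fw <- fitdistrplus::fitdist(x, "weibull")
  pg <- rk$params[rk$family == "Gamma"][[1]]
  pw <- rk$params[rk$family == "Weibull"][[1]]
  expect_equal(unname(pg["shape"]), unname(coef(fg)["shape"]),
               tolerance = 1e-3)
  expect_equal(unname(pg["rate"]), unname(coef(fg)["rate"]),
               tolerance = 1e-3)
  expect_equal(unname(pw["shape"]), unname(coef(fw)["shape"]),
               tolerance = 1e-3)
  expect_equal(rk$negLL[rk$family == "Gamma"], -logLik(fg)[1],
               tolerance = 1e-6)
})

test_that("three-parameter t fits recover and shift equivariantly", {
  set.seed(46)
  x <- rnorm(4e4) * sqrt(rinvgamma(4e4, 3, 3)) # gen-t: dof 6, scale 1
  f <- fitGeneralizedT(x)
  expect_true(f$converged)
  expect_gt(f$params@dof, 4.8); expect_lt(f$params@dof, 7.5)
  expect_lt(abs(f$params@location), 0.05)
  expect_equal(f$params@scaleSq, 1, tolerance = 0.1)

  f5 <- fitGeneralizedT(x + 5)
  expect_equal(f5$params@location, f$params@location + 5, tolerance = 0.02)
  expect_equal(f5$params@dof, f$params@dof, tolerance = 0.05)
  expect_equal(f5$params@scaleSq, f$params@scaleSq, tolerance = 0.01)

  set.seed(47)
  fg <- fitGeneralizedT(rnorm(2e4))
  expect_gt(fg$params@dof, 30) # asymptotically Gaussian
  expect_error(fitGeneralizedT(rnorm(20)), "50")
})

test_that("the ADF regression reproduces an independent implementation", {
  # statistics frozen from statsmodels adfuller (regression = "c",
  # fixed lag) on the identical series
  set.seed(7); walk <- cumsum(rnorm(80))
  set.seed(8); white <- rnorm(80)
  expect_equal(adfTest(walk, lags = 0)$statistic, -1.3237129506181877,
               tolerance = 1e-9)
  expect_equal(adfTest(walk, lags = 4)$statistic, -2.2048772883386887,
               tolerance = 1e-9)
  expect_equal(adfTest(white, lags = 0)$statistic, -9.344422100353372,
               tolerance = 1e-9)
  expect_equal(adfTest(white, lags = 4)$statistic, -4.34421489847238,
               tolerance = 1e-9)
  expect_identical(adfTest(white)$lags, 4L) # floor((T-1)^(1/3)) rule
})

test_that("the ADF decision separates white noise from random walks", {
  set.seed(48)
  nRep <- 200
  whiteStationary <- walkStationary <- logical(nRep)
  for (i in seq_len(nRep)) {
    e <- rnorm(500)
    whiteStationary[i] <- adfTest(e)$decision == "stationary"
    walkStationary[i] <- adfTest(cumsum(e))$decision == "stationary"
  }
  expect_gt(mean(whiteStationary), 0.99)
  expect_lt(mean(walkStationary), 0.10)
  expect_error(adfTest(rnorm(10)), "25")
  expect_error(adfTest(rep(1, 100)), "constant")
})

test_that("pairwise slice tests detect unequal power laws", {
  set.seed(49)
  mk <- function(slice, scale)
    slicevar:::newSliceVarianceSeries(slice, rinvgamma(240, 3, scale), 50L)
  svs <- list(mk(0L, 2), mk(1L, 8), mk(2L, 2))
  d <- pairwiseSliceTests(svs)
  expect_true(isSymmetric(unclass(d)))
  expect_false(any(diag(d)))
  expect_true(d[1, 2]) # scales 2 vs 8 at T = 240: rejected
  # decisions invariant to a common rescaling of both slices
  svs10 <- lapply(svs, function(s) slicevar:::newSliceVarianceSeries(
    sliceIndex(s), 10 * varianceValues(s), 50L))
  expect_identical(unclass(pairwiseSliceTests(svs10)), unclass(d))

  # a slice against an identical copy: degenerate, not rejected
  expect_warning(dd <- pairwiseSliceTests(list(svs[[1]], svs[[1]])),
                 "degenerate")
  expect_false(dd[1, 2])
  expect_error(pairwiseSliceTests(svs[1]), "2 slices")
})

test_that("identical power laws are rejected at about the nominal rate", {
  set.seed(50)
  hits <- replicate(60, {
    svs <- lapply(1:2, function(z)
      slicevar:::newSliceVarianceSeries(z - 1L, rinvgamma(240, 3, 2), 50L))
    pairwiseSliceTests(svs, alpha = 0.01)[1, 2]
  })
  expect_lte(sum(hits), qbinom(0.999, 60, 0.01) + 1)
})
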