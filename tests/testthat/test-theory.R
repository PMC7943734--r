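test_that("inverse-gamma moments match closed forms and Monte-Carlo", {
  expect_equal(igMoment(PowerProcessSpec(3, 2), 1), 1.0)
  expect_equal(igMoment(PowerProcessSpec(2, 2), 0.5),
               sqrt(2) * gamma(1.5) / gamma(2), tolerance = 1e-12)
  expect_equal(igMoment(PowerProcessSpec(2, 2), 0.5), 1.25331,
               tolerance = 1e-5)
  # log-gamma-space evaluation survives large shapes
  expect_true(is.finite(igMoment(PowerProcessSpec(500, 3), 0.5)))

  # Monte-Carlo oracle for the half moment
  set.seed(101)
  draws <- rinvgamma(2e5, 2, 2)
  se <- sd(sqrt(draws)) / sqrt(length(draws))
  expect_lt(abs(mean(sqrt(draws)) - igMoment(PowerProcessSpec(2, 2), 0.5)),
            3 * se)

  expect_error(igMoment(PowerProcessSpec(1, 2), 1), "shape")
  expect_error(igMoment(PowerProcessSpec(0.4, 2), 0.5), "shape")
  expect_error(PowerProcessSpec(-1, 2), "positive")
})

test_that("kappa is the Cauchy-Schwarz-bounded moment ratio", {
  sm <- PowerProcessSpec(2, 2); sn <- PowerProcessSpec(3, 2)
  expect_equal(kappaTheoretical(sm, sn), 0.83303, tolerance = 1e-4)
  # identical dependent processes attain the Cauchy-Schwarz equality
  expect_identical(kappaTheoretical(sm, sm, independent = FALSE), 1)
  # constant weight processes cancel in the empirical estimator
  expect_equal(kappaEmpirical(rep(4, 50), rep(9, 50)), 1)

  # Monte-Carlo cross-check of the closed form for independent draws
  set.seed(102)
  w <- sqrt(rinvgamma(5e5, 2, 2)); v <- sqrt(rinvgamma(5e5, 3, 2))
  kMC <- mean(w * v) / sqrt(mean(w^2) * mean(v^2))
  expect_equal(kMC, kappaTheoretical(sm, sn), tolerance = 5e-3)

  # bound holds over random admissible process pairs
  set.seed(103)
  for (i in 1:200) {
    a <- PowerProcessSpec(runif(1, 1.01, 10), runif(1, 0.1, 10))
    b <- PowerProcessSpec(runif(1, 1.01, 10), runif(1, 0.1, 10))
    k <- kappaTheoretical(a, b)
    expect_true(k > 0 && k <= 1)
  }
  expect_error(kappaTheoretical(PowerProcessSpec(0.9, 1), sn), "shape")
})

test_that("expected correlation and its sampling variance follow kappa", {
  expect_identical(expectedNonstationaryCorr(0.3, 1), 0.3)
  expect_identical(expectedNonstationaryCorr(0, 0.5), 0)
  expect_equal(expectedNonstationaryCorr(0.3, 0.83303), 0.24991,
               tolerance = 1e-4)
  expect_error(expectedNonstationaryCorr(1.2, 1), "rho")
  expect_error(expectedNonstationaryCorr(0.3, 1.2), "kappa")

  expect_equal(varSampleCorr(0, 1, 500), 1 / 498)
  expect_equal(varSampleCorr(0.3, 1, 500), (1 - 0.09) / 498)
  expect_equal(varSampleCorr(0.3, 0.83303, 500), 0.00188262,
               tolerance = 1e-6)
  expect_error(varSampleCorr(0.3, 1, 2), "T")
  # attenuation never shrinks the sampling variance
  ks <- seq(0, 1, by = 0.1)
  vs <- vapply(ks, function(k) varSampleCorr(0.4, k, 200), 0)
  expect_true(all(diff(vs) <= 0))
  expect_true(all(vs >= (1 - 0.16) / 198))

  a <- attenuation(PowerProcessSpec(2, 2), PowerProcessSpec(3, 2),
                   rho = 0.3, T = 500)
  expect_equal(attenuationKappa(a), 0.83304, tolerance = 1e-4)
  expect_equal(expectedCorr(a), attenuationKappa(a) * 0.3)
})

test_that("generalized-t density matches the location-scale Student's-t", {
  expect_equal(dGeneralizedT(0, 1, 1, 1), gamma(1.5) / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(dGeneralizedT(0, 1, 1, 1), 0.353553, tolerance = 1e-5)

  grid <- seq(-8, 8, length.out = 101)
  for (p in list(c(1, 1, 1), c(3, 3, 1), c(2.5, 0.7, 4))) {
    alpha <- p[1]; beta <- p[2]; sx2 <- p[3]
    s <- sqrt(beta * sx2 / alpha)
    expect_lt(max(abs(dGeneralizedT(grid, alpha, beta, sx2) -
                        dlst(grid, 0, s, 2 * alpha))), 1e-12)
    # symmetry and unit mass
    expect_equal(dGeneralizedT(grid, alpha, beta, sx2),
                 dGeneralizedT(-grid, alpha, beta, sx2))
    mass <- integrate(dGeneralizedT, -Inf, Inf, shape = alpha,
                      igScale = beta, sigmaXSq = sx2,
                      rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-8)
  }
  expect_error(dGeneralizedT(0, -1, 1, 1), "positive")
})

test_that("model parameters map onto the voxel-intensity t marginal", {
  p <- marginalTParams(PowerProcessSpec(1, 1), 1)
  expect_equal(c(p@location, p@dof, p@scaleSq), c(0, 2, 1))
  p <- marginalTParams(PowerProcessSpec(3, 3), 1)
  expect_equal(c(p@location, p@dof, p@scaleSq), c(0, 6, 1))

  # the pdf through the t parameterization reproduces the direct pdf
  grid <- seq(-6, 6, length.out = 201)
  p <- marginalTParams(PowerProcessSpec(2.5, 1.7), 0.8)
  expect_lt(max(abs(dlst(grid, p@location, sqrt(p@scaleSq), p@dof) -
                      dGeneralizedT(grid, 2.5, 1.7, 0.8))), 1e-10)

  # simulated model draws follow the derived marginal (KS, alpha = 0.01)
  set.seed(104)
  x <- rnorm(2e4) * sqrt(rinvgamma(2e4, 2.5, 1.7) * 0.8)
  ks <- suppressWarnings(ks.test(x, function(q)
    slicevar:::plst(q, p@location, sqrt(p@scaleSq), p@dof)))
  expect_gt(ks$p.value, 0.01)
})
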