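test_that("disturbance variance keeps the outcome factor at its total variance", {
  expect_equal(disturbanceVariance(1.0, 0.5, 1.0), 0.75)
  expect_equal(disturbanceVariance(1.0, 0.0, 1.0), 1.0)
  expect_equal(disturbanceVariance(1.3, 0.5, 1.3), 0.975)
  expect_error(disturbanceVariance(1.0, 1.1, 1.0), "not strictly positive")
})

test_that("ICC maps to the between variance that reproduces it", {
  expect_equal(iccBetweenVariance(0), 0)
  expect_equal(iccBetweenVariance(0.10), 0.1 / 0.9)
  expect_equal(iccBetweenVariance(0.35), 0.35 / 0.65)
  ## round trip: sigma_b / (sigma_b + 1) recovers the ICC
  for (icc in c(0.05, 0.10, 0.35, 0.8)) {
    b <- iccBetweenVariance(icc)
    expect_equal(b / (b + 1), icc)
  }
  expect_error(iccBetweenVariance(1), "icc")
  expect_error(iccBetweenVariance(-0.1), "icc")
})

test_that("single-level implied covariance matches the analytic entries", {
  pop <- singleLevelPopulation(pNI = 0, gamma = c(0.5, 0.5))
  S1 <- impliedCov(pop, 1)@matrices$sigma
  S2 <- impliedCov(pop, 2)@matrices$sigma
  ## invariant indicators carry exactly the group factor variance
  expect_equal(unname(diag(S1)), rep(1.0, 12))
  expect_equal(unname(diag(S2)), rep(1.3, 12))
  ## cross-block entry by path tracing: lx * gamma * phi * ly
  expect_equal(S1["x1", "y1"], 0.7 * 0.5 * 1.0 * 0.7)
})

test_that("implied covariance agrees with a path-tracing oracle to 1e-12", {
  for (cnd in list(study1Condition(0, c(0.1, 0.1), "none", 200),
                   study1Condition(2, c(0.5, 0.33), "X", 500),
                   study1Condition(4, c(0.33, 0.5), "Y", 200))) {
    pop <- populationFor(cnd)
    for (g in 1:2) {
      expect_equal(unname(impliedCov(pop, g)@matrices$sigma),
                   pathTracingCov(pop, g), tolerance = 1e-12)
    }
  }
})

test_that("implied covariances are positive definite across both grids", {
  for (cnd in designGrid(1)) {
    pop <- populationFor(cnd)
    for (g in 1:2) {
      ev <- eigen(impliedCov(pop, g)@matrices$sigma, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
  for (cnd in designGrid(2)) {
    pop <- populationFor(cnd)
    for (g in 1:2) {
      im <- impliedCov(pop, g)@matrices
      expect_gt(min(eigen(im$sigmaW, symmetric = TRUE, only.values = TRUE)$values), 0)
      expect_gte(min(eigen(im$sigmaB, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
    }
  }
})

test_that("two-level implied moments match the printed structure", {
  pop <- twoLevelPopulation(pNI = 0, gamma10 = c(0.3, 0.3), icc = 0.10)
  im <- impliedCov(pop, 1)@matrices
  expect_equal(im$sigmaW["x1", "x1"], 0.7^2 + 0.5)   # marker within variance
  expect_equal(im$sigmaW["y", "y"], 1.0)             # within outcome variance
  ## no between-level indicator residuals: sigmaB restricted to rank one plus
  ## the outcome cell
  lam <- pop@loadings[1, ]
  expect_equal(unname(im$sigmaB[1:6, 1:6]),
               iccBetweenVariance(0.10) * tcrossprod(lam), tolerance = 1e-12)
  expect_equal(unname(im$sigmaB[1:6, 7]), rep(0, 6))
})

test_that("within plus between covariance equals the brute-force marginal", {
  for (cnd in list(study2Condition(0, c(0.3, 0.3), 0.10, 30, 5),
                   study2Condition(2, c(0.3, 0.2), 0.35, 100, 20))) {
    pop <- populationFor(cnd)
    for (g in 1:2) {
      im <- impliedCov(pop, g)@matrices
      expect_equal(unname(im$sigmaW + im$sigmaB), marginalCovOracle(pop, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("population validity enforces the invariance structure", {
  ## marker must stay invariant and equal 0.7
  expect_error(singleLevelPopulation(pNI = 2, location = "X", loading = 0.6),
               "marker")
  ## location required when pNI > 0, forbidden when pNI = 0
  expect_error(new("SingleLevelPopulation",
                   loadingsX = matrix(0.7, 2, 6), loadingsY = matrix(0.7, 2, 6),
                   factorVarX = c(1, 1.3), factorVarY = c(1, 1.3),
                   uniqueVarX = matrix(0.51, 2, 6), uniqueVarY = matrix(0.51, 2, 6),
                   gamma = c(0.1, 0.1), pNI = 0, location = "X"),
               "location")
  ## exactly pNI loadings must differ, on the stated factor
  pop <- singleLevelPopulation(pNI = 2, location = "X", gamma = c(0.5, 0.5))
  expect_equal(sum(pop@loadingsX[1, ] != pop@loadingsX[2, ]), 2)
  expect_true(all(pop@loadingsY[1, ] == pop@loadingsY[2, ]))
})

test_that("constraint schemes enforce marker and freed-set invariants", {
  expect_error(constraintScheme("partial_metric",
                                data.frame(factor = "X", index = 1L)),
               "marker")
  expect_error(constraintScheme("full_metric",
                                data.frame(factor = "X", index = 5L)),
               "empty iff")
  expect_error(constraintScheme("partial_metric"), "empty iff")
  sch <- partialMetricScheme(study1Condition(4, c(0.5, 0.5), "Y", 200))
  expect_identical(sch@kind, "partial_metric")
  expect_setequal(sch@freedLoadings$index, 3:6)
  expect_true(all(sch@freedLoadings$factor == "Y"))
  expect_error(partialMetricScheme(singleLevelPopulation(pNI = 0)), "undefined")
})
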