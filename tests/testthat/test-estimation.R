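test_that("the ML discrepancy has its analytic value and fixed point", {
  ## univariate hand evaluation: ln 1 + 2 - ln 2 - 1
  expect_equal(mlDiscrepancy(matrix(1), matrix(2)), log(1) + 2 - log(2) - 1)
  expect_equal(mlDiscrepancy(matrix(1), matrix(2)), 0.3068528, tolerance = 1e-6)
  ## zero at the implied moments, positive elsewhere
  pop <- singleLevelPopulation(pNI = 2, location = "X", gamma = c(0.5, 0.5))
  S <- lapply(1:2, function(g) impliedCov(pop, g)@matrices$sigma)
  expect_equal(mlDiscrepancy(S, S, c(200, 200)), 0)
  set.seed(1)
  for (i in 1:5) {
    p <- sample(2:6, 1)
    A <- crossprod(matrix(rnorm(4 * p * p), 4 * p, p)) / (4 * p)
    B <- crossprod(matrix(rnorm(4 * p * p), 4 * p, p)) / (4 * p)
    expect_gte(mlDiscrepancy(A, B), 0)
  }
})

test_that("analytic gradients match finite differences", {
  ## single level, partial scheme, random-ish sample moments
  cnd <- study1Condition(2, c(0.5, 0.33), "X", 200)
  mom <- momentsOf(generateSingle(cnd, 5))
  sch <- partialMetricScheme(cnd)
  pm <- invarimod:::.parmapSingle(sch, FALSE)
  w <- mom@n / sum(mom@n)
  ldS <- vapply(mom@S, function(S) determinant(S)$modulus[1], 0)
  th <- pm$start + 0.05
  f <- function(t) invarimod:::.objgradSingle(t, pm, mom@S, w, ldS)$F
  expect_equal(invarimod:::.objgradSingle(th, pm, mom@S, w, ldS)$grad,
               numGradient(f, th), tolerance = 1e-6)
  ## two level
  cnd2 <- study2Condition(2, c(0.3, 0.2), 0.10, 30, 5)
  mom2 <- momentsOf(generateTwoLevel(cnd2, 5))
  pm2 <- invarimod:::.parmapTwoLevel(partialMetricScheme(cnd2), FALSE)
  th2 <- pm2$start + 0.05
  f2 <- function(t) invarimod:::.objgradTwoLevel(t, pm2, mom2, TRUE)$F
  expect_equal(invarimod:::.objgradTwoLevel(th2, pm2, mom2, TRUE)$grad,
               numGradient(f2, th2), tolerance = 1e-4)
})

test_that("fitting the correct scheme to implied moments recovers the population", {
  ## spot-check one cell per study here; the exhaustive sweep over both grids
  ## lives in the acceptance suite
  cnd <- study1Condition(4, c(0.33, 0.5), "Y", 500)
  fit <- fitSEM(populationMoments(cnd), partialMetricScheme(cnd))
  expect_true(isConverged(fit))
  est <- coef(fit)
  expect_lt(abs(est["gamma.g1"] - 0.33), 1e-6)
  expect_lt(abs(est["gamma.g2"] - 0.5), 1e-6)
  expect_equal(unname(fit@contrast["delta"]), -0.17, tolerance = 1e-6)
  expect_lt(abs(est["phix.g2"] - 1.3), 1e-5)
  expect_lt(abs(est["ly3.g2"] - 0.3), 1e-5)
  expect_lt(fit@discrepancy, 1e-10)
})

test_that("misspecified invariance fits distort the contrast in the known directions", {
  ## population-level (deterministic) pseudo-true values of the MI model
  for (loc in c("X", "Y")) {
    for (pni in c(2, 4)) {
      cnd <- study1Condition(pni, c(0.5, 0.5), loc, 500)
      fit <- fitSEM(populationMoments(cnd), fullMetricScheme())
      expect_true(isConverged(fit))
      if (loc == "X") expect_lt(fit@contrast["delta"], 0)
      else expect_gt(fit@contrast["delta"], 0)
    }
  }
  ## two level: predictor-side non-invariance underestimates the contrast
  cnd2 <- study2Condition(2, c(0.3, 0.3), 0.10, 100, 20)
  fit2 <- fitSEM(populationMoments(cnd2), fullMetricScheme(), weighting = "moment")
  expect_lt(fit2@contrast["delta"], 0)
})

test_that("pooled moments return the design sizes and unbiased expectations", {
  cnd <- study2Condition(0, c(0.3, 0.3), 0.10, 30, 5)
  pop <- populationFor(cnd)
  mom1 <- pooledMomentsTwoLevel(generateTwoLevel(cnd, 1))
  expect_equal(mom1@clusterSize, cnd@clusterSize)
  expect_equal(mom1@m, rep(30, 2))
  ## Monte Carlo expectation over replicates (many clusters so the between
  ## estimator's spread is small relative to the tolerance)
  big <- cnd; big@m <- 200
  R <- 100
  accW <- accB <- matrix(0, 7, 7)
  for (r in seq_len(R)) {
    mom <- momentsOf(generateTwoLevel(big, 1000 + r))
    accW <- accW + mom@SPW[[1]] / R
    accB <- accB + mom@SB[[1]] / R
  }
  im <- impliedCov(pop, 1)@matrices
  expect_lt(max(abs(accW - im$sigmaW)), 0.02)
  expect_lt(max(abs(accB - (im$sigmaW + 5 * im$sigmaB))), 0.05)
})

test_that("the two-level likelihood equals a direct per-cluster oracle", {
  cnd <- study2Condition(2, c(0.3, 0.2), 0.10, 30, 5)
  tiny <- cnd; tiny@m <- 3; tiny@clusterSize <- 2
  s <- generateTwoLevel(tiny, 17)
  mom <- momentsOf(s)
  ## evaluate at an arbitrary (not fitted) parameter point: the population of
  ## a different cell
  pop <- populationFor(study2Condition(0, c(0.3, 0.3), 0.35, 30, 5))
  sw <- lapply(1:2, function(g) impliedCov(pop, g)@matrices$sigmaW)
  sb <- lapply(1:2, function(g) impliedCov(pop, g)@matrices$sigmaB)
  expect_equal(twoLevelLogLik(mom, sw, sb), directTwoLevelLogLik(s, sw, sb),
               tolerance = 1e-6)
  ## and at a fitted solution
  fit <- fitSEM(mom, fullMetricScheme())
  pm <- invarimod:::.parmapTwoLevel(fullMetricScheme(), FALSE)
  sfit <- lapply(1:2, function(g) invarimod:::.sigmaTwoLevel(pm, coef(fit), g))
  expect_equal(logLik(fit),
               directTwoLevelLogLik(s, lapply(sfit, `[[`, "SW"),
                                    lapply(sfit, `[[`, "SB")),
               tolerance = 1e-6)
})

test_that("the Wald contrast has its closed-form values", {
  expect_equal(unname(waldContrast(0, se = 0.1)[c("W", "p")]), c(0, 1))
  w <- waldContrast(0.2, se = 0.1)
  expect_equal(unname(w["W"]), 4.00)
  expect_equal(unname(w["p"]), 0.0455, tolerance = 1e-3)
  expect_equal(unname(w["p"]), pchisq(4, 1, lower.tail = FALSE))
})

test_that("Wald and likelihood-ratio tests agree asymptotically", {
  ## one large replicate under each hypothesis
  for (gam in list(c(0.5, 0.5), c(0.5, 0.33))) {
    cnd <- study1Condition(0, gam, "none", 500)
    big <- cnd; big@N <- 50000
    mom <- momentsOf(generateSingle(big, 31))
    fit <- fitSEM(mom, fullMetricScheme())
    fit0 <- fitSEM(mom, fullMetricScheme(), equalSlopes = TRUE)
    G2 <- lrtContrast(fit, fit0)
    expect_gte(G2["G2"], 0)
    expect_equal(unname(G2["G2"]), unname(fit@contrast["W"]), tolerance = 0.02,
                 ignore_attr = TRUE)
  }
  ## identical fits give a zero statistic
  cnd <- study1Condition(0, c(0.1, 0.1), "none", 200)
  mom <- momentsOf(generateSingle(cnd, 8))
  f1 <- fitSEM(mom, fullMetricScheme(), equalSlopes = TRUE)
  expect_equal(unname(lrtContrast(f1, f1, tol = 0)["G2"]), 0)
})

test_that("the contrast estimator is unbiased under correct specification", {
  ## smallest grid cell, full replication count; mean of the contrast within
  ## two Monte Carlo standard errors of the truth
  cnd <- study1Condition(0, c(0.5, 0.33), "none", 200)
  R <- 500
  idx <- cellIndex(cnd)
  deltas <- vapply(seq_len(R), function(r) {
    fit <- fitSEM(generateSingle(cnd, replicateSeed(42, idx, r)),
                  fullMetricScheme(), se = "expected")
    unname(fit@contrast["delta"])
  }, 0)
  mcse <- sd(deltas) / sqrt(R)
  expect_lt(abs(mean(deltas) - 0.17), 2 * mcse)
})

test_that("equal-slopes fits share one slope and expose no contrast", {
  cnd <- study1Condition(0, c(0.1, 0.1), "none", 200)
  mom <- momentsOf(generateSingle(cnd, 4))
  fit <- fitSEM(mom, fullMetricScheme(), equalSlopes = TRUE)
  expect_true(isConverged(fit))
  expect_true("gamma" %in% names(coef(fit)))
  expect_false(any(c("gamma.g1", "gamma.g2") %in% names(coef(fit))))
  expect_true(is.na(fit@contrast["delta"]))
  expect_error(waldContrast(fit), "undefined")
})

test_that("estimate covariance is symmetric positive semi-definite", {
  cnd <- study2Condition(2, c(0.3, 0.3), 0.10, 30, 5)
  for (se in c("robust", "expected")) {
    fit <- fitSEM(momentsOf(generateTwoLevel(cnd, 21)),
                  partialMetricScheme(cnd), se = se)
    V <- vcov(fit)
    expect_true(isSymmetric(V, tol = 1e-10))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
    expect_identical(fit@vcovType, se)
  }
})
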