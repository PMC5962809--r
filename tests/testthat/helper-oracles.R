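## Independent oracles used across the test files. These deliberately use
## slow, element-by-element path-tracing / density evaluation rather than the
## package's vectorized algebra.

## path-tracing oracle for the single-level implied covariance: every entry
## assembled from explicit loops over the two latent variables
pathTracingCov <- function(pop, group) {
  lx <- pop@loadingsX[group, ]; ly <- pop@loadingsY[group, ]
  phi <- pop@factorVarX[group]
  gam <- pop@gamma[group]
  psi <- pop@factorVarY[group] - gam^2 * phi
  ## latent covariance matrix of (F_X, F_Y) by the structural equations
  latent <- matrix(NA_real_, 2, 2)
  latent[1, 1] <- phi
  latent[1, 2] <- latent[2, 1] <- gam * phi
  latent[2, 2] <- gam^2 * phi + psi
  load <- rbind(cbind(lx, 0), cbind(0, ly))   # 12 x 2
  uniq <- c(pop@uniqueVarX[group, ], pop@uniqueVarY[group, ])
  S <- matrix(0, 12, 12)
  for (j in 1:12) for (k in 1:12) {
    s <- 0
    for (a in 1:2) for (b in 1:2) s <- s + load[j, a] * latent[a, b] * load[k, b]
    if (j == k) s <- s + uniq[j]
    S[j, k] <- s
  }
  S
}

## marginal covariance of one observation of a two-level population, obtained
## by brute-force expansion of the generative equations for a single cluster
## member: y = lambda (Fb + Fw) + delta_w ; Y = zeta + gamma Fw + r
marginalCovOracle <- function(pop, group) {
  lam <- pop@loadings[group, ]
  gam <- pop@gamma10[group]
  phib <- pop@betweenFactorVar; szeta <- pop@betweenOutcomeVar
  thw <- pop@withinUniqueVar[group, ]
  resid <- pop@withinOutcomeVar - gam^2 * pop@withinFactorVar
  S <- matrix(0, 7, 7)
  for (j in 1:6) for (k in 1:6) {
    S[j, k] <- lam[j] * lam[k] * (phib + pop@withinFactorVar) +
      if (j == k) thw[j] else 0
  }
  for (j in 1:6) S[j, 7] <- S[7, j] <- lam[j] * gam * pop@withinFactorVar
  S[7, 7] <- szeta + gam^2 * pop@withinFactorVar + resid
  S
}

## multivariate normal log-density via Cholesky (for the cluster-likelihood
## oracle)
mvnLogDensity <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

## direct per-cluster log-likelihood of a balanced two-level sample: each
## cluster contributes a (c*p)-dimensional normal with covariance
## I_c (x) Sigma_W + J_c (x) Sigma_B, centered at the group grand mean
directTwoLevelLogLik <- function(sample, sigmaW, sigmaB) {
  ll <- 0
  cs <- sample@condition@clusterSize
  for (g in 1:2) {
    dat <- sample@data[[g]]; cl <- sample@cluster[[g]]
    mu <- rep(colMeans(dat), cs)
    big <- kronecker(diag(cs), sigmaW[[g]]) +
      kronecker(matrix(1, cs, cs), sigmaB[[g]])
    for (j in unique(cl)) {
      x <- as.vector(t(dat[cl == j, , drop = FALSE]))
      ll <- ll + mvnLogDensity(x, mu, big)
    }
  }
  ll
}

## finite-difference gradient of a scalar function
numGradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
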