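## Model-implied covariance algebra.
##
## Single level, per group: indicators x1..x6 then y1..y6,
##   cov(x_j, x_k) = lx_j lx_k phi_x + [j = k] theta_xj
##   cov(x_j, y_k) = lx_j gamma phi_x ly_k
##   cov(y_j, y_k) = ly_j ly_k (gamma^2 phi_x + psi) + [j = k] theta_yj
##
## Two level, per group: columns x1..x6, y.
##   Sigma_W: treat y as a seventh "indicator" of F_X(w) with loading gamma10
##   and unique variance 1 - gamma10^2; Sigma_B: rank-one indicator block
##   lambda lambda' phi_b (no residuals), between outcome variance in the
##   (7,7) cell, no indicator-outcome between covariance (no between path).

#' @describeIn impliedCov 12 x 12 implied covariance of a single-level group.
#' @export
setMethod("impliedCov", "SingleLevelPopulation", function(population, group = 1L) {
  g <- as.integer(group)
  stopifnot(g %in% 1:2)
  lx <- population@loadingsX[g, ]; ly <- population@loadingsY[g, ]
  phi <- population@factorVarX[g]
  gam <- population@gamma[g]
  psi <- disturbanceVariance(population@factorVarY[g], gam, phi)
  S <- matrix(0, 12, 12)
  S[1:6, 1:6] <- phi * tcrossprod(lx) + diag(population@uniqueVarX[g, ])
  S[7:12, 7:12] <- (gam^2 * phi + psi) * tcrossprod(ly) + diag(population@uniqueVarY[g, ])
  S[1:6, 7:12] <- (gam * phi) * tcrossprod(lx, ly)
  S[7:12, 1:6] <- t(S[1:6, 7:12])
  dimnames(S) <- list(.slColnames(), .slColnames())
  new("ImpliedMoments", matrices = list(sigma = S), mean = numeric(12),
      level = "single")
})

#' @describeIn impliedCov within and between 7 x 7 implied covariances of a
#'   two-level group.
#' @export
setMethod("impliedCov", "TwoLevelPopulation", function(population, group = 1L) {
  g <- as.integer(group)
  stopifnot(g %in% 1:2)
  lam <- population@loadings[g, ]
  gam <- population@gamma10[g]
  lt <- c(lam, gam)
  residY <- population@withinOutcomeVar - gam^2 * population@withinFactorVar
  SW <- population@withinFactorVar * tcrossprod(lt) +
    diag(c(population@withinUniqueVar[g, ], residY))
  lb <- c(lam, 0)
  SB <- population@betweenFactorVar * tcrossprod(lb)
  SB[7, 7] <- SB[7, 7] + population@betweenOutcomeVar
  nm <- .tlColnames()
  dimnames(SW) <- dimnames(SB) <- list(nm, nm)
  new("ImpliedMoments", matrices = list(sigmaW = SW, sigmaB = SB),
      mean = numeric(7), level = "two")
})

.slColnames <- function() c(paste0("x", 1:6), paste0("y", 1:6))
.tlColnames <- function() c(paste0("x", 1:6), "y")

setMethod("show", "ImpliedMoments", function(object) {
  cat("Model-implied moments (", object@level, " level):\n", sep = "")
  for (nm in names(object@matrices))
    cat("  ", nm, ": ", nrow(object@matrices[[nm]]), " x ",
        ncol(object@matrices[[nm]]), "\n", sep = "")
})

#' Population-implied sufficient statistics
#'
#' Packages the model-implied covariance structure of both groups of a design
#' cell as a moments object, so that an analysis model can be fitted directly
#' to the population (the "infinite-sample" fit used for fixed-point recovery
#' checks and for pseudo-true values of misspecified models). The nominal
#' sample sizes are taken from the condition. Two-level fits to such moments
#' should use `weighting = "moment"` (see [fitSEM()]).
#'
#' @param condition a design condition.
#' @return a [TwoGroupMoments-class] or [TwoLevelMoments-class].
#' @export
populationMoments <- function(condition) {
  pop <- populationFor(condition)
  if (is(condition, "Study1Condition")) {
    S <- lapply(1:2, function(g) impliedCov(pop, g)@matrices$sigma)
    new("TwoGroupMoments", S = S, n = rep(condition@N, 2), centered = list())
  } else {
    m <- condition@m; cs <- condition@clusterSize
    SPW <- SB <- vector("list", 2)
    for (g in 1:2) {
      im <- impliedCov(pop, g)@matrices
      SPW[[g]] <- im$sigmaW
      SB[[g]] <- im$sigmaW + cs * im$sigmaB   # E[S_B] = Sigma_W + c Sigma_B
    }
    new("TwoLevelMoments", SPW = SPW, SB = SB, m = rep(m, 2),
        clusterSize = cs, n = rep(m * cs, 2), W = list(), ybar = list())
  }
}
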