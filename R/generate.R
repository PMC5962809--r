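## Seeded generators. Latent scores and residuals are drawn directly from the
## generative equations (not via a Cholesky factor of the implied covariance),
## so the generator and the implied-moment algebra are independent routes that
## must agree -- this is tested.

.GROUP_OFFSET <- 499979L   # group-2 substream offset within a replication

#' Replication seed for a design cell
#'
#' Replication `rep` of grid cell `cell` uses
#' `(baseSeed + cell * 1e6 + rep) mod (2^31 - 1)`, giving reproducible
#' streams that do not overlap across cells for any realistic replication
#' count. Group 2 additionally offsets its stream so that the two groups are
#' independent and group 1's data do not depend on group 2's parameters.
#'
#' @param baseSeed integer base seed.
#' @param cell cell index within the study grid (see [cellIndex()]).
#' @param rep replication number (1-based).
#' @export
replicateSeed <- function(baseSeed, cell, rep) {
  (baseSeed + cell * 1e6 + rep) %% 2147483647
}

#' Generate one single-level two-group replicate
#'
#' Per group, draws the latent predictor, the structural disturbance, and the
#' unique factors as independent normals with the population variances, then
#' assembles the 12 indicators through the measurement equations. All means
#' are zero.
#'
#' @param condition a [Study1Condition-class].
#' @param seed integer seed; identical `(condition, seed)` yields an identical
#'   sample.
#' @return a [TwoGroupSample-class].
#' @export
generateSingle <- function(condition, seed) {
  pop <- populationFor(condition)
  N <- condition@N
  dat <- vector("list", 2)
  for (g in 1:2) {
    set.seed((seed + (g - 1L) * .GROUP_OFFSET) %% 2147483647)
    phi <- pop@factorVarX[g]
    gam <- pop@gamma[g]
    psi <- disturbanceVariance(pop@factorVarY[g], gam, phi)
    FX <- rnorm(N, 0, sqrt(phi))
    FY <- gam * FX + rnorm(N, 0, sqrt(psi))
    X <- tcrossprod(FX, pop@loadingsX[g, ]) +
      matrix(rnorm(N * 6), N, 6) %*% diag(sqrt(pop@uniqueVarX[g, ]))
    Y <- tcrossprod(FY, pop@loadingsY[g, ]) +
      matrix(rnorm(N * 6), N, 6) %*% diag(sqrt(pop@uniqueVarY[g, ]))
    d <- cbind(X, Y)
    colnames(d) <- .slColnames()
    dat[[g]] <- d
  }
  new("TwoGroupSample", data = dat, condition = condition, seed = seed)
}

#' Generate one two-level two-group replicate
#'
#' Per group: for each of the m clusters draws the between-level factor score
#' and the between-level outcome residual; for each of the c observations per
#' cluster draws the within-level factor score, the level-1 unique factors and
#' the level-1 outcome residual; assembles
#' `X_ij = lambda (F_b[j] + F_w[ij]) + delta_w[ij]` and
#' `Y_ij = zeta[j] + gamma10 F_w[ij] + r[ij]`. Clusters are balanced with
#' contiguous ids 1..m.
#'
#' @param condition a [Study2Condition-class].
#' @param seed integer seed.
#' @return a [TwoLevelSample-class].
#' @export
generateTwoLevel <- function(condition, seed) {
  pop <- populationFor(condition)
  m <- condition@m; cs <- condition@clusterSize; n <- m * cs
  dat <- clus <- vector("list", 2)
  for (g in 1:2) {
    set.seed((seed + (g - 1L) * .GROUP_OFFSET) %% 2147483647)
    lam <- pop@loadings[g, ]
    gam <- pop@gamma10[g]
    Fb <- rnorm(m, 0, sqrt(pop@betweenFactorVar))
    zeta <- rnorm(m, 0, sqrt(pop@betweenOutcomeVar))
    Fw <- rnorm(n, 0, sqrt(pop@withinFactorVar))
    r <- rnorm(n, 0, sqrt(pop@withinOutcomeVar - gam^2 * pop@withinFactorVar))
    cl <- rep(seq_len(m), each = cs)
    X <- tcrossprod(Fb[cl] + Fw, lam) +
      matrix(rnorm(n * 6), n, 6) %*% diag(sqrt(pop@withinUniqueVar[g, ]))
    Y <- pop@gamma00 + zeta[cl] + gam * Fw + r
    d <- cbind(X, Y)
    colnames(d) <- .tlColnames()
    dat[[g]] <- d
    clus[[g]] <- cl
  }
  new("TwoLevelSample", data = dat, cluster = clus, condition = condition,
      seed = seed)
}

#' @describeIn momentsOf per-group centered data and ML covariance (divisor n).
#' @export
setMethod("momentsOf", "TwoGroupSample", function(x) {
  Z <- lapply(x@data, function(d) sweep(d, 2, colMeans(d)))
  S <- lapply(Z, function(z) crossprod(z) / nrow(z))
  new("TwoGroupMoments", S = S, n = vapply(x@data, nrow, 0), centered = Z)
})

#' @describeIn momentsOf balanced-design pooled-within / between statistics.
#' @export
setMethod("momentsOf", "TwoLevelSample", function(x) {
  SPW <- SB <- W <- yb <- vector("list", 2)
  for (g in 1:2) {
    p <- .pooledOneGroup(x@data[[g]], x@cluster[[g]])
    SPW[[g]] <- p$SPW; SB[[g]] <- p$SB; W[[g]] <- p$W; yb[[g]] <- p$ybar
  }
  new("TwoLevelMoments", SPW = SPW, SB = SB,
      m = rep(x@condition@m, 2), clusterSize = x@condition@clusterSize,
      n = vapply(x@data, nrow, 0), W = W, ybar = yb)
})

.pooledOneGroup <- function(dat, cl) {
  m <- length(unique(cl)); cs <- nrow(dat) / m
  if (any(table(cl) != cs)) stop("unbalanced clusters are not supported")
  ybar <- rowsum(dat, cl) / cs
  Z <- dat - ybar[cl, , drop = FALSE]
  SPW <- crossprod(Z) / (nrow(dat) - m)
  ybc <- sweep(ybar, 2, colMeans(ybar))
  SB <- cs * crossprod(ybc) / (m - 1)
  W <- lapply(seq_len(m), function(j) crossprod(Z[cl == j, , drop = FALSE]))
  list(SPW = SPW, SB = SB, W = W, ybar = ybc)
}

#' Pooled within- and between-cluster covariance of a balanced sample
#'
#' The sufficient statistics of the balanced two-level normal model:
#' `S_PW = sum_j sum_i (y_ij - ybar_j)(y_ij - ybar_j)' / (n - m)` with
#' expectation Sigma_W, and
#' `S_B = c sum_j (ybar_j - ybar)(ybar_j - ybar)' / (m - 1)` with expectation
#' Sigma_W + c Sigma_B.
#'
#' @param sample a [TwoLevelSample-class].
#' @return a [TwoLevelMoments-class]; slots `SPW`, `SB` per group, common
#'   cluster size in `clusterSize`.
#' @export
pooledMomentsTwoLevel <- function(sample) momentsOf(sample)

#' Write a replicate to a plain comma-separated table
#'
#' One row per observation with columns x1..x6 (and y1..y6 or y), `group`,
#' and for two-level samples `cluster`; for cross-checking against external
#' SEM software.
#'
#' @param sample a generated sample.
#' @param path output file path.
#' @export
writeSample <- function(sample, path) {
  rows <- lapply(1:2, function(g) {
    d <- as.data.frame(sample@data[[g]])
    d$group <- g
    if (is(sample, "TwoLevelSample")) d$cluster <- sample@cluster[[g]]
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

setMethod("show", "TwoGroupSample", function(object) {
  cat("Two-group single-level sample: N =", nrow(object@data[[1]]),
      "per group, 12 indicators, seed", object@seed, "\n")
})

setMethod("show", "TwoLevelSample", function(object) {
  cat("Two-group two-level sample:", object@condition@m, "clusters of",
      object@condition@clusterSize, "per group, seed", object@seed, "\n")
})
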