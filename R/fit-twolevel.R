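## Two-group two-level constrained ML on balanced sufficient statistics.
##
## Per group, with S_PW (pooled within, divisor n - m), S_B (scaled between,
## divisor m - 1), Sigma* = Sigma_W + c Sigma_B, the profiled (means
## saturated) -2 log-likelihood is, up to constants,
##   (n - m)[ln|Sigma_W| + tr(Sigma_W^-1 S_PW)] + m ln|Sigma*|
##     + (m - 1) tr(Sigma*^-1 S_B).
## "moment" weighting replaces m by m - 1 on the log-determinant so a fit to
## expected moments has its optimum exactly at S_PW = Sigma_W, S_B = Sigma*.

.sigmaTwoLevel <- function(pm, thn, g) {
  lam <- c(pm$marker, thn[pm$lIdx[g, 2:6]])
  lt <- c(lam, thn[pm$gamIdx[g]])
  lb <- c(lam, 0)
  SW <- thn[pm$phiwIdx[g]] * tcrossprod(lt) +
    diag(c(thn[pm$thwIdx[g, ]], thn[pm$srIdx[g]]))
  SB <- thn[pm$phibIdx[g]] * tcrossprod(lb)
  SB[7, 7] <- SB[7, 7] + thn[pm$szIdx[g]]
  list(SW = SW, SB = SB, lt = lt, lb = lb)
}

.objgradTwoLevel <- function(theta, pm, mom, exact = TRUE) {
  thn <- .naturalScale(pm, theta)
  F <- 0
  grad <- numeric(length(theta))
  for (g in 1:2) {
    m <- mom@m[g]; cs <- mom@clusterSize; n <- mom@n[g]
    a <- n - m; b <- if (exact) m else m - 1; d <- m - 1
    s <- .sigmaTwoLevel(pm, thn, g)
    Sstar <- s$SW + cs * s$SB
    chW <- tryCatch(chol(s$SW), error = function(e) NULL)
    chS <- tryCatch(chol(Sstar), error = function(e) NULL)
    if (is.null(chW) || is.null(chS)) return(list(F = 1e10, grad = grad))
    P <- chol2inv(chW); Q <- chol2inv(chS)
    F <- F + a * (2 * sum(log(diag(chW))) + sum(P * mom@SPW[[g]])) +
      b * 2 * sum(log(diag(chS))) + d * sum(Q * mom@SB[[g]])
    K <- b * Q - d * Q %*% mom@SB[[g]] %*% Q
    GW <- a * (P - P %*% mom@SPW[[g]] %*% P) + K
    GB <- cs * K
    phiw <- thn[pm$phiwIdx[g]]; phib <- thn[pm$phibIdx[g]]
    gwl <- 2 * phiw * (GW %*% s$lt)
    gbl <- 2 * phib * (GB %*% s$lb)
    ii <- pm$lIdx[g, 2:6]; grad[ii] <- grad[ii] + gwl[2:6] + gbl[2:6]
    i <- pm$gamIdx[g]; grad[i] <- grad[i] + gwl[7]
    i <- pm$phiwIdx[g]; grad[i] <- grad[i] + sum(s$lt * (GW %*% s$lt))
    i <- pm$phibIdx[g]; grad[i] <- grad[i] + sum(s$lb * (GB %*% s$lb))
    ii <- pm$thwIdx[g, ]; grad[ii] <- grad[ii] + diag(GW)[1:6]
    i <- pm$srIdx[g]; grad[i] <- grad[i] + GW[7, 7]
    i <- pm$szIdx[g]; grad[i] <- grad[i] + GB[7, 7]
  }
  grad[pm$trans] <- grad[pm$trans] * thn[pm$trans]
  list(F = F, grad = grad)
}

## per-group derivative structures: dSigma_W and dSigma_B for each parameter
.derivsTwoLevel <- function(pm, thn, g) {
  s <- .sigmaTwoLevel(pm, thn, g)
  phiw <- thn[pm$phiwIdx[g]]; phib <- thn[pm$phibIdx[g]]
  ders <- vector("list", 0); idxs <- integer(0)
  add <- function(i, DW, DB) {
    ders[[length(ders) + 1L]] <<- list(DW = DW, DB = DB)
    idxs[length(idxs) + 1L] <<- i
  }
  Z7 <- matrix(0, 7, 7)
  E <- function(k) { D <- Z7; D[k, k] <- 1; D }
  rank1 <- function(k, v) { D <- Z7; D[k, ] <- v; D[, k] <- D[, k] + v; D }
  for (k in 2:6) add(pm$lIdx[g, k], phiw * rank1(k, s$lt), phib * rank1(k, s$lb))
  add(pm$gamIdx[g], phiw * rank1(7, s$lt), Z7)
  add(pm$phiwIdx[g], tcrossprod(s$lt), Z7)
  add(pm$phibIdx[g], Z7, tcrossprod(s$lb))
  for (k in 1:6) add(pm$thwIdx[g, k], E(k), Z7)
  add(pm$srIdx[g], E(7), Z7)
  add(pm$szIdx[g], Z7, E(7))
  list(ders = ders, idxs = idxs, s = s)
}

## expected information with Wishart weights (n-m)/2 within, (m-1)/2 between;
## robust sandwich from per-cluster scores of the profiled likelihood
.vcovTwoLevel <- function(pm, thn, mom, type = c("robust", "expected")) {
  type <- match.arg(type)
  K <- length(thn)
  A <- matrix(0, K, K)
  Bm <- if (type == "robust") matrix(0, K, K) else NULL
  for (g in 1:2) {
    m <- mom@m[g]; cs <- mom@clusterSize; n <- mom@n[g]
    dd <- .derivsTwoLevel(pm, thn, g)
    s <- dd$s
    Sstar <- s$SW + cs * s$SB
    P <- chol2inv(chol(s$SW)); Q <- chol2inv(chol(Sstar))
    np <- length(dd$ders); idxs <- dd$idxs
    TW <- lapply(dd$ders, function(D) P %*% D$DW)
    TS <- lapply(dd$ders, function(D) Q %*% (D$DW + cs * D$DB))
    for (u in seq_len(np)) {
      TWu <- t(TW[[u]]); TSu <- t(TS[[u]])
      for (v in u:np) {
        val <- (n - m) / 2 * sum(TWu * TW[[v]]) + (m - 1) / 2 * sum(TSu * TS[[v]])
        A[idxs[u], idxs[v]] <- A[idxs[u], idxs[v]] + val
        if (idxs[u] != idxs[v]) A[idxs[v], idxs[u]] <- A[idxs[v], idxs[u]] + val
      }
    }
    if (type == "robust") {
      PWP <- lapply(mom@W[[g]], function(Wj) P %*% Wj %*% P)
      Vrows <- mom@ybar[[g]] %*% Q
      SC <- matrix(0, m, np)
      for (k in seq_len(np)) {
        DW <- dd$ders[[k]]$DW
        DS <- DW + cs * dd$ders[[k]]$DB
        t1 <- (cs - 1) * sum(P * DW)
        t3 <- sum(Q * DS)
        qf <- rowSums((Vrows %*% DS) * Vrows)
        trW <- vapply(PWP, function(U) sum(U * DW), 0)
        SC[, k] <- -0.5 * (t1 - trW + t3 - cs * qf)
      }
      Bm[idxs, idxs] <- Bm[idxs, idxs] + crossprod(SC)
    }
  }
  Ainv <- solve(A)
  V <- if (type == "robust") Ainv %*% Bm %*% Ainv else Ainv
  (V + t(V)) / 2
}

#' Exact log-likelihood of a two-level model at given moments
#'
#' The profiled (cluster means centered at the grand mean) log-likelihood of
#' the balanced two-group two-level normal model, including all constants, so
#' that it can be compared against a direct per-cluster evaluation of the
#' (c p)-dimensional normal density.
#'
#' @param mom a [TwoLevelMoments-class].
#' @param sigmaW,sigmaB per-group lists of within and between covariance
#'   matrices at which to evaluate.
#' @return the scalar log-likelihood.
#' @export
twoLevelLogLik <- function(mom, sigmaW, sigmaB) {
  ll <- 0
  p <- nrow(sigmaW[[1]])
  for (g in 1:2) {
    m <- mom@m[g]; cs <- mom@clusterSize; n <- mom@n[g]
    Sstar <- sigmaW[[g]] + cs * sigmaB[[g]]
    chW <- chol(sigmaW[[g]]); chS <- chol(Sstar)
    ll <- ll - 0.5 * (
      (n - m) * (p * log(2 * pi) + 2 * sum(log(diag(chW)))) +
        (n - m) * sum(chol2inv(chW) * mom@SPW[[g]]) +
        m * (p * log(2 * pi) + 2 * sum(log(diag(chS)))) +
        (m - 1) * sum(chol2inv(chS) * mom@SB[[g]])
    )
  }
  ll
}

.fitTwoLevelCore <- function(mom, scheme, equalSlopes = FALSE,
                             se = c("expected", "robust"),
                             weighting = c("ml", "moment"), control = list()) {
  se <- match.arg(se)
  weighting <- match.arg(weighting)
  if (se == "robust" && length(mom@W) == 0) se <- "expected"
  exact <- weighting == "ml"
  pm <- .parmapTwoLevel(scheme, equalSlopes)
  ob <- function(th) .objgradTwoLevel(th, pm, mom, exact)$F
  gr <- function(th) .objgradTwoLevel(th, pm, mom, exact)$grad
  ctl <- modifyList(list(iter.max = 500, eval.max = 1000, rel.tol = 1e-12), control)
  opt <- nlminb(pm$start, ob, gr, lower = .lowerBounds(pm), control = ctl)
  thn <- .naturalScale(pm, opt$par)
  names(thn) <- pm$labels
  og <- .objgradTwoLevel(opt$par, pm, mom, exact)
  ## scale the gradient check to the objective size (weights here are counts,
  ## not proportions as in the single-level discrepancy)
  gradNorm <- max(abs(og$grad)) / max(1, sum(mom@n))
  heywood <- any(opt$par[pm$trans] <= -18 + 1e-6)
  converged <- is.finite(og$F) && og$F < 1e9 && gradNorm < 1e-5
  V <- tryCatch(.vcovTwoLevel(pm, thn, mom, se),
                error = function(e) matrix(NA_real_, length(thn), length(thn)))
  sw <- lapply(1:2, function(g) .sigmaTwoLevel(pm, thn, g))
  ll <- twoLevelLogLik(mom, lapply(sw, `[[`, "SW"), lapply(sw, `[[`, "SB"))
  contrast <- .makeContrast(thn, V, pm$gamIdx, equalSlopes)
  new("FitResult", estimates = thn, vcov = V, vcovType = se,
      logLik = ll, discrepancy = og$F,
      converged = converged, iterations = opt$iterations, gradNorm = gradNorm,
      heywood = heywood, contrast = contrast, scheme = scheme,
      level = "two", equalSlopes = equalSlopes, nobs = mom@n)
}

#' @describeIn fitSEM reduce a balanced two-level sample to its pooled
#'   moments and fit.
#' @export
setMethod("fitSEM", "TwoLevelSample", function(x, scheme, equalSlopes = FALSE,
                                               se = c("expected", "robust"),
                                               weighting = c("ml", "moment"), ...) {
  .fitTwoLevelCore(momentsOf(x), scheme, equalSlopes, match.arg(se),
                   match.arg(weighting), ...)
})

#' @describeIn fitSEM fit directly to two-level sufficient statistics.
#' @export
setMethod("fitSEM", "TwoLevelMoments", function(x, scheme, equalSlopes = FALSE,
                                                se = c("expected", "robust"),
                                                weighting = c("ml", "moment"), ...) {
  .fitTwoLevelCore(x, scheme, equalSlopes, match.arg(se), match.arg(weighting), ...)
})
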