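## Single-level two-group constrained ML.
##
## Discrepancy: F = sum_g (n_g/n) [ln|Sigma_g| + tr(S_g Sigma_g^{-1})
##                                 - ln|S_g| - p],
## minimized over the free parameters of the scheme with an analytic gradient.
## The mean structure is saturated per group, so it drops out of the fit.

#' Normal-theory ML discrepancy of a multiple-group covariance structure
#'
#' `F = sum_g w_g [ln|Sigma_g| + tr(S_g Sigma_g^-1) - ln|S_g| - p]` with
#' weights `w_g = n_g / n`. F is nonnegative and zero iff every implied matrix
#' equals its sample counterpart.
#'
#' @param implied list of implied covariance matrices (one per group), or a
#'   single matrix.
#' @param sample list of sample covariance matrices (ML divisor), or a matrix.
#' @param n per-group sample sizes (defaults to equal weights).
#' @return the scalar discrepancy.
#' @examples
#' mlDiscrepancy(matrix(1), matrix(2))  # log(1) + 2 - log(2) - 1
#' @export
mlDiscrepancy <- function(implied, sample, n = NULL) {
  if (is.matrix(implied)) implied <- list(implied)
  if (is.matrix(sample)) sample <- list(sample)
  stopifnot(length(implied) == length(sample))
  if (is.null(n)) n <- rep(1, length(implied))
  w <- n / sum(n)
  F <- 0
  for (g in seq_along(implied)) {
    Sg <- implied[[g]]; S <- sample[[g]]
    p <- nrow(S)
    ch <- chol(Sg)
    Sinv <- chol2inv(ch)
    F <- F + w[g] * (2 * sum(log(diag(ch))) + sum(Sinv * S) -
                       determinant(S)$modulus[1] - p)
  }
  unname(F)
}

## implied covariance for one group from natural-scale parameters
.sigmaSingle <- function(pm, thn, g) {
  lx <- c(pm$marker, thn[pm$lxIdx[g, 2:6]])
  ly <- c(pm$marker, thn[pm$lyIdx[g, 2:6]])
  phi <- thn[pm$phiIdx[g]]; gam <- thn[pm$gamIdx[g]]; psi <- thn[pm$psiIdx[g]]
  S <- matrix(0, 12, 12)
  S[1:6, 1:6] <- phi * tcrossprod(lx) + diag(thn[pm$thxIdx[g, ]])
  S[7:12, 7:12] <- (gam^2 * phi + psi) * tcrossprod(ly) + diag(thn[pm$thyIdx[g, ]])
  S[1:6, 7:12] <- (gam * phi) * tcrossprod(lx, ly)
  S[7:12, 1:6] <- t(S[1:6, 7:12])
  S
}

## objective and analytic gradient on the transformed scale; ldS are the
## precomputed log-determinants of the sample matrices
.objgradSingle <- function(theta, pm, S, w, ldS) {
  thn <- .naturalScale(pm, theta)
  F <- 0
  grad <- numeric(length(theta))
  for (g in 1:2) {
    lx <- c(pm$marker, thn[pm$lxIdx[g, 2:6]])
    ly <- c(pm$marker, thn[pm$lyIdx[g, 2:6]])
    phi <- thn[pm$phiIdx[g]]; gam <- thn[pm$gamIdx[g]]; psi <- thn[pm$psiIdx[g]]
    Sg <- .sigmaSingle(pm, thn, g)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(list(F = 1e10, grad = grad))
    Sinv <- chol2inv(ch)
    F <- F + w[g] * (2 * sum(log(diag(ch))) + sum(Sinv * S[[g]]) - ldS[g] - 12)
    ## dF/dSigma, then chain through Sigma = Lambda Phi Lambda' + Theta
    G <- w[g] * (Sinv - Sinv %*% S[[g]] %*% Sinv)
    Gxx <- G[1:6, 1:6]; Gxy <- G[1:6, 7:12]; Gyy <- G[7:12, 7:12]
    p11 <- phi; p12 <- gam * phi; p22 <- gam^2 * phi + psi
    GL1 <- cbind(Gxx %*% lx, Gxy %*% ly)
    GL2 <- cbind(crossprod(Gxy, lx), Gyy %*% ly)
    dLx <- 2 * (GL1[, 1] * p11 + GL1[, 2] * p12)
    dLy <- 2 * (GL2[, 1] * p12 + GL2[, 2] * p22)
    M11 <- sum(lx * (Gxx %*% lx))
    M12 <- sum(lx * (Gxy %*% ly))
    M22 <- sum(ly * (Gyy %*% ly))
    ii <- pm$lxIdx[g, 2:6]; grad[ii] <- grad[ii] + dLx[2:6]
    ii <- pm$lyIdx[g, 2:6]; grad[ii] <- grad[ii] + dLy[2:6]
    i <- pm$phiIdx[g]; grad[i] <- grad[i] + M11 + 2 * gam * M12 + gam^2 * M22
    i <- pm$gamIdx[g]; grad[i] <- grad[i] + 2 * phi * (M12 + gam * M22)
    i <- pm$psiIdx[g]; grad[i] <- grad[i] + M22
    ii <- pm$thxIdx[g, ]; grad[ii] <- grad[ii] + diag(Gxx)
    ii <- pm$thyIdx[g, ]; grad[ii] <- grad[ii] + diag(Gyy)
  }
  grad[pm$trans] <- grad[pm$trans] * thn[pm$trans]   # log-scale chain rule
  list(F = F, grad = grad)
}

## per-group derivative matrices dSigma/dtheta_k at the natural-scale solution
.derivsSingle <- function(pm, thn, g) {
  lx <- c(pm$marker, thn[pm$lxIdx[g, 2:6]])
  ly <- c(pm$marker, thn[pm$lyIdx[g, 2:6]])
  phi <- thn[pm$phiIdx[g]]; gam <- thn[pm$gamIdx[g]]; psi <- thn[pm$psiIdx[g]]
  Lam <- matrix(0, 12, 2); Lam[1:6, 1] <- lx; Lam[7:12, 2] <- ly
  Phi <- matrix(c(phi, gam * phi, gam * phi, gam^2 * phi + psi), 2)
  B <- Lam %*% Phi
  ders <- vector("list", 0); idxs <- integer(0)
  add <- function(i, D) { ders[[length(ders) + 1L]] <<- D; idxs[length(idxs) + 1L] <<- i }
  rank1 <- function(row, v) {
    D <- matrix(0, 12, 12); D[row, ] <- v; D[, row] <- D[, row] + v; D
  }
  for (k in 2:6) {
    add(pm$lxIdx[g, k], rank1(k, B[, 1]))
    add(pm$lyIdx[g, k], rank1(6 + k, B[, 2]))
  }
  add(pm$phiIdx[g], Lam %*% matrix(c(1, gam, gam, gam^2), 2) %*% t(Lam))
  add(pm$gamIdx[g], Lam %*% matrix(c(0, phi, phi, 2 * gam * phi), 2) %*% t(Lam))
  add(pm$psiIdx[g], Lam %*% matrix(c(0, 0, 0, 1), 2) %*% t(Lam))
  for (k in 1:12) {
    D <- matrix(0, 12, 12); D[k, k] <- 1
    add(if (k <= 6) pm$thxIdx[g, k] else pm$thyIdx[g, k - 6], D)
  }
  list(ders = ders, idxs = idxs)
}

## expected information (A) and, when centered data are available, the
## sandwich A^-1 B A^-1 from per-observation scores
.vcovSingle <- function(pm, thn, n, Z, type = c("robust", "expected")) {
  type <- match.arg(type)
  K <- length(thn)
  A <- matrix(0, K, K)
  Bm <- if (type == "robust") matrix(0, K, K) else NULL
  for (g in 1:2) {
    Sg <- .sigmaSingle(pm, thn, g)
    Sinv <- chol2inv(chol(Sg))
    dd <- .derivsSingle(pm, thn, g)
    np <- length(dd$ders); idxs <- dd$idxs
    Ts <- lapply(dd$ders, function(D) Sinv %*% D)
    for (a in seq_len(np)) {
      Ta <- t(Ts[[a]])
      for (b in a:np) {
        v <- n[g] / 2 * sum(Ta * Ts[[b]])
        A[idxs[a], idxs[b]] <- A[idxs[a], idxs[b]] + v
        if (idxs[a] != idxs[b]) A[idxs[b], idxs[a]] <- A[idxs[b], idxs[a]] + v
      }
    }
    if (type == "robust") {
      TT <- lapply(Ts, function(Tj) Tj %*% Sinv)  # Sinv dSigma Sinv
      Zg <- Z[[g]]
      SC <- matrix(0, nrow(Zg), np)
      for (j in seq_len(np)) {
        q <- rowSums((Zg %*% TT[[j]]) * Zg)
        SC[, j] <- 0.5 * (q - sum(TT[[j]] * Sg))
      }
      Bm[idxs, idxs] <- Bm[idxs, idxs] + crossprod(SC)
    }
  }
  Ainv <- solve(A)
  V <- if (type == "robust") Ainv %*% Bm %*% Ainv else Ainv
  (V + t(V)) / 2
}

.fitSingleCore <- function(mom, scheme, equalSlopes = FALSE,
                           se = c("expected", "robust"), control = list()) {
  se <- match.arg(se)
  if (se == "robust" && length(mom@centered) == 0) se <- "expected"
  pm <- .parmapSingle(scheme, equalSlopes)
  n <- mom@n
  w <- n / sum(n)
  ldS <- vapply(mom@S, function(S) determinant(S)$modulus[1], 0)
  ob <- function(th) .objgradSingle(th, pm, mom@S, w, ldS)$F
  gr <- function(th) .objgradSingle(th, pm, mom@S, w, ldS)$grad
  ctl <- modifyList(list(iter.max = 500, eval.max = 1000, rel.tol = 1e-12), control)
  opt <- nlminb(pm$start, ob, gr, lower = .lowerBounds(pm), control = ctl)
  thn <- .naturalScale(pm, opt$par)
  names(thn) <- pm$labels
  og <- .objgradSingle(opt$par, pm, mom@S, w, ldS)
  gradNorm <- max(abs(og$grad))
  heywood <- any(opt$par[pm$trans] <= -18 + 1e-6)
  converged <- is.finite(og$F) && og$F < 1e9 && gradNorm < 1e-5
  V <- tryCatch(.vcovSingle(pm, thn, n, mom@centered, se),
                error = function(e) matrix(NA_real_, length(thn), length(thn)))
  ## log-likelihood (means profiled): -n_g/2 [p ln 2pi + ln|Sigma| + tr(S Sigma^-1)]
  ll <- 0
  for (g in 1:2) {
    Sg <- .sigmaSingle(pm, thn, g)
    ch <- chol(Sg)
    ll <- ll - n[g] / 2 * (12 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                             sum(chol2inv(ch) * mom@S[[g]]))
  }
  contrast <- .makeContrast(thn, V, pm$gamIdx, equalSlopes)
  new("FitResult", estimates = thn, vcov = V, vcovType = se,
      logLik = ll, discrepancy = og$F,
      converged = converged, iterations = opt$iterations, gradNorm = gradNorm,
      heywood = heywood, contrast = contrast, scheme = scheme,
      level = "single", equalSlopes = equalSlopes, nobs = n)
}

## the moderation contrast delta = gamma_1 - gamma_2 and its Wald test
.makeContrast <- function(thn, V, gamIdx, equalSlopes) {
  if (equalSlopes || any(is.na(V))) {
    return(c(delta = NA_real_, se = NA_real_, W = NA_real_, df = 1, p = NA_real_))
  }
  delta <- unname(thn[gamIdx[1]] - thn[gamIdx[2]])
  v <- V[gamIdx[1], gamIdx[1]] + V[gamIdx[2], gamIdx[2]] -
    2 * V[gamIdx[1], gamIdx[2]]
  se <- sqrt(max(v, 0))
  W <- if (se > 0) delta^2 / v else if (delta == 0) 0 else Inf
  c(delta = delta, se = se, W = W, df = 1,
    p = pchisq(W, 1, lower.tail = FALSE))
}

#' @describeIn fitSEM reduce a single-level sample to its moments and fit.
#' @export
setMethod("fitSEM", "TwoGroupSample", function(x, scheme, equalSlopes = FALSE,
                                               se = c("expected", "robust"), ...) {
  .fitSingleCore(momentsOf(x), scheme, equalSlopes, match.arg(se), ...)
})

#' @describeIn fitSEM fit directly to single-level sufficient statistics
#'   (e.g. population-implied moments).
#' @export
setMethod("fitSEM", "TwoGroupMoments", function(x, scheme, equalSlopes = FALSE,
                                                se = c("expected", "robust"), ...) {
  .fitSingleCore(x, scheme, equalSlopes, match.arg(se), ...)
})
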