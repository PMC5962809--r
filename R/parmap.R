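## Internal parameter maps.
##
## A parameter map assigns every model slot (a loading, variance or slope of a
## given group) an index into the free-parameter vector theta, with 0 marking
## a fixed slot. Cross-group (and, for two-level models, cross-level) equality
## constraints are implemented by sharing one theta index across slots.
## Variances are optimized on the log scale ("trans" flags); slopes and
## loadings on the identity scale. Starting values are deliberately generic
## (loadings 0.5, variances 1, slopes 0), not the truth.

.newParmap <- function() {
  env <- new.env(parent = emptyenv())
  env$labels <- character(0); env$trans <- logical(0); env$start <- numeric(0)
  env
}

.addPar <- function(env, label, logScale, start) {
  env$labels <- c(env$labels, label)
  env$trans <- c(env$trans, logScale)
  env$start <- c(env$start, start)
  length(env$labels)
}

.freedIdx <- function(scheme, factor) {
  fl <- scheme@freedLoadings
  as.integer(fl$index[fl$factor == factor])
}

## Single-level map: slots per group are loadings x2..x6 / y2..y6 (marker
## fixed), phi_x, gamma, psi, 12 unique variances.
.parmapSingle <- function(scheme, equalSlopes = FALSE) {
  pm <- .newParmap()
  lxIdx <- lyIdx <- matrix(0L, 2, 6)
  freedX <- .freedIdx(scheme, "X"); freedY <- .freedIdx(scheme, "Y")
  for (k in 2:6) {
    i <- .addPar(pm, paste0("lx", k), FALSE, 0.5)
    lxIdx[1, k] <- i
    lxIdx[2, k] <- if (k %in% freedX) .addPar(pm, paste0("lx", k, ".g2"), FALSE, 0.5) else i
  }
  for (k in 2:6) {
    i <- .addPar(pm, paste0("ly", k), FALSE, 0.5)
    lyIdx[1, k] <- i
    lyIdx[2, k] <- if (k %in% freedY) .addPar(pm, paste0("ly", k, ".g2"), FALSE, 0.5) else i
  }
  phiIdx <- gamIdx <- psiIdx <- integer(2)
  thxIdx <- thyIdx <- matrix(0L, 2, 6)
  if (equalSlopes) gshared <- .addPar(pm, "gamma", FALSE, 0)
  for (g in 1:2) {
    phiIdx[g] <- .addPar(pm, paste0("phix.g", g), TRUE, 1)
    gamIdx[g] <- if (equalSlopes) gshared else .addPar(pm, paste0("gamma.g", g), FALSE, 0)
    psiIdx[g] <- .addPar(pm, paste0("psi.g", g), TRUE, 1)
    for (k in 1:6) thxIdx[g, k] <- .addPar(pm, paste0("thx", k, ".g", g), TRUE, 1)
    for (k in 1:6) thyIdx[g, k] <- .addPar(pm, paste0("thy", k, ".g", g), TRUE, 1)
  }
  list(labels = pm$labels, trans = pm$trans, start = pm$start,
       lxIdx = lxIdx, lyIdx = lyIdx, phiIdx = phiIdx, gamIdx = gamIdx,
       psiIdx = psiIdx, thxIdx = thxIdx, thyIdx = thyIdx,
       marker = scheme@marker)
}

## Two-level map: loadings l2..l6 (marker fixed, cross-level equality is
## implicit: one lambda enters both Sigma_W and Sigma_B), per group phi_w,
## gamma10, level-1 outcome residual, 6 within unique variances, phi_b and
## the between outcome variance. Between indicator residuals are fixed 0 and
## there is no between-level structural path.
.parmapTwoLevel <- function(scheme, equalSlopes = FALSE) {
  pm <- .newParmap()
  lIdx <- matrix(0L, 2, 6)
  freed <- .freedIdx(scheme, "X")
  for (k in 2:6) {
    i <- .addPar(pm, paste0("l", k), FALSE, 0.5)
    lIdx[1, k] <- i
    lIdx[2, k] <- if (k %in% freed) .addPar(pm, paste0("l", k, ".g2"), FALSE, 0.5) else i
  }
  phiwIdx <- gamIdx <- srIdx <- phibIdx <- szIdx <- integer(2)
  thwIdx <- matrix(0L, 2, 6)
  if (equalSlopes) gshared <- .addPar(pm, "gamma10", FALSE, 0)
  for (g in 1:2) {
    phiwIdx[g] <- .addPar(pm, paste0("phiw.g", g), TRUE, 1)
    gamIdx[g] <- if (equalSlopes) gshared else .addPar(pm, paste0("gamma10.g", g), FALSE, 0)
    srIdx[g] <- .addPar(pm, paste0("resY.g", g), TRUE, 1)
    for (k in 1:6) thwIdx[g, k] <- .addPar(pm, paste0("thw", k, ".g", g), TRUE, 1)
    phibIdx[g] <- .addPar(pm, paste0("phib.g", g), TRUE, 0.2)
    szIdx[g] <- .addPar(pm, paste0("zetaY.g", g), TRUE, 0.2)
  }
  list(labels = pm$labels, trans = pm$trans, start = pm$start,
       lIdx = lIdx, phiwIdx = phiwIdx, gamIdx = gamIdx, srIdx = srIdx,
       thwIdx = thwIdx, phibIdx = phibIdx, szIdx = szIdx,
       marker = scheme@marker)
}

## transformed (optimizer) scale -> natural scale
.naturalScale <- function(pm, theta) {
  theta[pm$trans] <- exp(theta[pm$trans])
  theta
}

## lower bounds on the transformed scale: variances floored at exp(-18)
.lowerBounds <- function(pm) {
  lo <- rep(-Inf, length(pm$trans))
  lo[pm$trans] <- -18
  lo
}
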