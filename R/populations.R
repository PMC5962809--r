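#' Disturbance variance of the latent outcome
#'
#' The structural disturbance variance that makes the total variance of the
#' latent outcome equal its stated factor variance:
#' psi = var(F_Y) - gamma^2 * var(F_X).
#'
#' @param factorVarY total variance of the latent outcome.
#' @param gamma structural slope.
#' @param factorVarX variance of the latent predictor.
#' @return the disturbance variance psi (strictly positive).
#' @examples
#' disturbanceVariance(1.0, 0.5, 1.0)  # 0.75
#' @export
disturbanceVariance <- function(factorVarY, gamma, factorVarX) {
  psi <- factorVarY - gamma^2 * factorVarX
  if (any(psi <= 0))
    stop("invalid population: disturbance variance psi = ",
         paste(signif(psi, 4), collapse = ", "), " is not strictly positive")
  psi
}

#' Between-level variance implied by an intraclass correlation
#'
#' With the within-level variance fixed at 1, the between variance that makes
#' the intraclass correlation equal `icc` is icc / (1 - icc).
#'
#' @param icc intraclass correlation, in `[0, 1)`.
#' @export
iccBetweenVariance <- function(icc) {
  if (any(icc < 0) || any(icc >= 1)) stop("icc must lie in [0, 1)")
  icc / (1 - icc)
}

## non-invariant indicators are always the LAST pNI ones, so the marker
## (indicator 1) stays invariant -- required for valid identification
.nonInvariantIdx <- function(pNI) if (pNI > 0) seq.int(6 - pNI + 1, 6) else integer(0)

#' Construct the single-level study population
#'
#' Builds the two-group population of the single-level design: all loadings
#' 0.7 in group 1; in group 2 the last `pNI` loadings of the `location` factor
#' are lowered to `loadingNI`. Factor variances are 1.0 (group 1) and 1.3
#' (group 2) for both factors; the structural disturbance absorbs the slope so
#' the outcome factor keeps its total variance. Unique variances hold every
#' indicator's total variance at the group factor variance (1.0 / 1.3), giving
#' 0.51 and 0.663 for the invariant indicators and 1.183 for non-invariant
#' ones.
#'
#' @param pNI number of non-invariant loadings: 0, 2 or 4.
#' @param location factor carrying the non-invariance ("X", "Y"); "none"
#'   required when `pNI = 0`.
#' @param gamma length-2 structural slope (group 1, group 2).
#' @param factorVar length-2 total factor variances per group.
#' @param loading invariant loading value.
#' @param loadingNI non-invariant (group 2) loading value.
#' @return a validated [SingleLevelPopulation-class].
#' @examples
#' pop <- singleLevelPopulation(pNI = 2, location = "X", gamma = c(0.5, 0.5))
#' impliedCov(pop, group = 1)
#' @export
singleLevelPopulation <- function(pNI = 0,
                                  location = if (pNI == 0) "none" else "X",
                                  gamma = c(0.1, 0.1),
                                  factorVar = c(1.0, 1.3),
                                  loading = 0.7, loadingNI = 0.3) {
  lx <- ly <- rbind(rep(loading, 6), rep(loading, 6))
  ni <- .nonInvariantIdx(pNI)
  if (length(ni)) {
    if (location == "X") lx[2, ni] <- loadingNI else ly[2, ni] <- loadingNI
  }
  ## unique variances keep each indicator's total variance at the group
  ## factor variance
  ux <- factorVar - lx^2 * factorVar
  uy <- factorVar - ly^2 * factorVar
  new("SingleLevelPopulation",
      loadingsX = lx, loadingsY = ly,
      factorVarX = factorVar, factorVarY = factorVar,
      uniqueVarX = ux, uniqueVarY = uy,
      gamma = gamma, pNI = pNI, location = location)
}

#' Construct the two-level study population
#'
#' Builds the two-group, two-level population: loadings
#' (0.7, 0.3, 0.5, 0.6, 0.7, 0.7) used at both levels, with the last `pNI`
#' lowered to 0.3 in group 2; within-level factor and outcome variances 1;
#' level-1 unique variances 0.5; between-level factor and outcome-residual
#' variances icc/(1 - icc); between-level indicator residuals zero; no
#' between-level structural path.
#'
#' @param pNI number of non-invariant loadings: 0 or 2.
#' @param gamma10 length-2 within-level slope (group 1, group 2).
#' @param icc intraclass correlation: 0.10 or 0.35.
#' @param loadings length-6 loading vector of group 1.
#' @param withinUniqueVar level-1 unique variance of every indicator.
#' @return a validated [TwoLevelPopulation-class].
#' @export
twoLevelPopulation <- function(pNI = 0, gamma10 = c(0.3, 0.3), icc = 0.10,
                               loadings = c(0.7, 0.3, 0.5, 0.6, 0.7, 0.7),
                               withinUniqueVar = 0.5) {
  lam <- rbind(loadings, loadings)
  ni <- .nonInvariantIdx(pNI)
  if (length(ni)) lam[2, ni] <- 0.3
  bv <- iccBetweenVariance(icc)
  new("TwoLevelPopulation",
      loadings = unname(lam),
      withinFactorVar = 1, withinOutcomeVar = 1,
      withinUniqueVar = matrix(withinUniqueVar, 2, 6),
      gamma10 = gamma10, gamma00 = 0,
      icc = icc, betweenFactorVar = bv, betweenOutcomeVar = bv,
      pNI = pNI)
}

#' @describeIn populationFor single-level study population for a design cell.
#' @export
setMethod("populationFor", "Study1Condition", function(condition) {
  singleLevelPopulation(pNI = condition@pNI, location = condition@location,
                        gamma = condition@gamma)
})

#' @describeIn populationFor two-level study population for a design cell.
#' @export
setMethod("populationFor", "Study2Condition", function(condition) {
  twoLevelPopulation(pNI = condition@pNI, gamma10 = condition@gamma10,
                     icc = condition@icc)
})

setMethod("show", "SingleLevelPopulation", function(object) {
  cat("Two-group single-level population\n")
  cat("  pNI =", object@pNI, " location =", object@location,
      " gamma = (", paste(object@gamma, collapse = ", "), ")\n")
  cat("  factor variances:", paste(object@factorVarX, collapse = " / "), "\n")
})

setMethod("show", "TwoLevelPopulation", function(object) {
  cat("Two-group two-level population\n")
  cat("  pNI =", object@pNI, " gamma10 = (",
      paste(object@gamma10, collapse = ", "), ")  ICC =", object@icc, "\n")
  cat("  loadings g1:", paste(object@loadings[1, ], collapse = " "), "\n")
  cat("  loadings g2:", paste(object@loadings[2, ], collapse = " "), "\n")
})
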