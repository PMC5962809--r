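#' @import methods
NULL

## Central S4 classes. All per-group slots are length-2 (group 1, group 2)
## or 2-row matrices with one row per group; indicators are columns 1..6.

#' Two-group single-level population
#'
#' Population parameterization of a two-group bivariate latent-variable model:
#' two factors (a latent predictor F_X and a latent outcome F_Y), six
#' congeneric indicators each, and a structural regression of F_Y on F_X with
#' group-specific slope gamma. Metric non-invariance is carried by `pNI`
#' loadings on the `location` factor, which take a lower value in group 2.
#'
#' @slot loadingsX,loadingsY 2 x 6 matrices of factor loadings (rows = groups).
#' @slot factorVarX,factorVarY length-2 total factor variances.
#' @slot uniqueVarX,uniqueVarY 2 x 6 matrices of unique-factor variances.
#' @slot gamma length-2 structural slope of F_Y on F_X.
#' @slot pNI number of non-invariant loadings (0, 2 or 4).
#' @slot location factor carrying the non-invariance: "X", "Y" or "none".
#'
#' @seealso [singleLevelPopulation()] for the validated constructor with the
#'   study defaults.
#' @export
setClass("SingleLevelPopulation",
  representation(
    loadingsX = "matrix", loadingsY = "matrix",
    factorVarX = "numeric", factorVarY = "numeric",
    uniqueVarX = "matrix", uniqueVarY = "matrix",
    gamma = "numeric", pNI = "numeric", location = "character"
  )
)

setValidity("SingleLevelPopulation", function(object) {
  msg <- character(0)
  for (s in c("loadingsX", "loadingsY", "uniqueVarX", "uniqueVarY")) {
    if (!all(dim(slot(object, s)) == c(2L, 6L)))
      msg <- c(msg, sprintf("%s must be a 2 x 6 matrix", s))
  }
  if (length(msg)) return(msg)
  if (any(object@loadingsX[, 1] != 0.7) || any(object@loadingsY[, 1] != 0.7))
    msg <- c(msg, "marker loadings (indicator 1) must equal 0.7 in both groups")
  if (any(object@uniqueVarX <= 0) || any(object@uniqueVarY <= 0))
    msg <- c(msg, "unique variances must be strictly positive")
  psi <- object@factorVarY - object@gamma^2 * object@factorVarX
  if (any(psi <= 0))
    msg <- c(msg, "implied disturbance variance psi must be strictly positive")
  if (!object@pNI %in% c(0, 2, 4))
    msg <- c(msg, "pNI must be 0, 2 or 4")
  if (!object@location %in% c("X", "Y", "none"))
    msg <- c(msg, "location must be 'X', 'Y' or 'none'")
  if (object@pNI == 0 && object@location != "none")
    msg <- c(msg, "location must be 'none' when pNI = 0")
  ndx <- sum(object@loadingsX[1, ] != object@loadingsX[2, ])
  ndy <- sum(object@loadingsY[1, ] != object@loadingsY[2, ])
  nd <- switch(object@location, X = ndx, Y = ndy, none = 0L)
  if (ndx + ndy != object@pNI || nd != object@pNI)
    msg <- c(msg, "exactly pNI loadings must differ between groups, all on the `location` factor")
  if (length(msg)) msg else TRUE
})

#' Two-group two-level population
#'
#' Population parameterization of a two-group, two-level model: a six-indicator
#' latent predictor measured at the within- and between-cluster level with
#' identical loadings at both levels, an observed within-level outcome Y
#' regressed on the within-level factor with group-specific slope gamma10,
#' and between-level variances governed by the intraclass correlation.
#' Between-level indicator residual variances are exactly zero (invariance
#' across clusters).
#'
#' @slot loadings 2 x 6 matrix of loadings, shared by both levels.
#' @slot withinFactorVar,withinOutcomeVar within-level variances of the factor
#'   and of Y (both 1 in the study design).
#' @slot withinUniqueVar 2 x 6 matrix of level-1 unique variances.
#' @slot gamma10 length-2 within-level slope of Y on the factor.
#' @slot gamma00 grand intercept (0 in the study design).
#' @slot icc intraclass correlation of the latent predictor and of Y.
#' @slot betweenFactorVar,betweenOutcomeVar between-level variances, derived
#'   from `icc` as icc/(1 - icc).
#' @slot pNI number of non-invariant loadings (0 or 2).
#'
#' @seealso [twoLevelPopulation()]
#' @export
setClass("TwoLevelPopulation",
  representation(
    loadings = "matrix",
    withinFactorVar = "numeric", withinOutcomeVar = "numeric",
    withinUniqueVar = "matrix",
    gamma10 = "numeric", gamma00 = "numeric",
    icc = "numeric", betweenFactorVar = "numeric", betweenOutcomeVar = "numeric",
    pNI = "numeric"
  )
)

setValidity("TwoLevelPopulation", function(object) {
  msg <- character(0)
  if (!all(dim(object@loadings) == c(2L, 6L)))
    return("loadings must be a 2 x 6 matrix")
  if (object@loadings[1, 1] != object@loadings[2, 1])
    msg <- c(msg, "marker loading (indicator 1) must be invariant across groups")
  if (any(object@withinUniqueVar <= 0))
    msg <- c(msg, "within-level unique variances must be strictly positive")
  resid <- object@withinOutcomeVar - object@gamma10^2 * object@withinFactorVar
  if (any(resid <= 0))
    msg <- c(msg, "level-1 outcome residual variance must be strictly positive")
  if (object@icc < 0 || object@icc >= 1)
    msg <- c(msg, "icc must lie in [0, 1)")
  if (!object@pNI %in% c(0, 2))
    msg <- c(msg, "pNI must be 0 or 2")
  if (length(msg)) msg else TRUE
})

#' Constraint scheme for a two-group analysis model
#'
#' Describes which loadings are estimated with cross-group equality (the
#' default), which are freed per group, and the marker identification. Under
#' `full_metric` all loadings are cross-group equal ("MI"); under
#' `partial_metric` the listed loadings are estimated separately in each group
#' ("pMI"). The marker (indicator 1 of every factor) is always fixed to 0.7 in
#' both groups and may never be freed. Latent means/intercepts are fixed to
#' zero and observed intercepts and unique variances are free per group
#' without cross-group constraints, so the mean structure is saturated and the
#' fit reduces to the covariance structure.
#'
#' @slot kind `"full_metric"` or `"partial_metric"`.
#' @slot freedLoadings data.frame with columns `factor` ("X" or "Y") and
#'   `index` (2..6): loadings estimated separately per group.
#' @slot marker fixed marker loading value (0.7).
#'
#' @seealso [constraintScheme()], [fullMetricScheme()], [partialMetricScheme()]
#' @export
setClass("ConstraintScheme",
  representation(kind = "character", freedLoadings = "data.frame",
                 marker = "numeric")
)

setValidity("ConstraintScheme", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("full_metric", "partial_metric"))
    msg <- c(msg, "kind must be 'full_metric' or 'partial_metric'")
  fl <- object@freedLoadings
  if (!all(c("factor", "index") %in% names(fl)))
    return("freedLoadings needs columns 'factor' and 'index'")
  if (nrow(fl)) {
    if (any(fl$index == 1L))
      msg <- c(msg, "the marker (indicator 1) may never be freed")
    if (!all(fl$factor %in% c("X", "Y")) || !all(fl$index %in% 2:6))
      msg <- c(msg, "freedLoadings entries must be factor in {X, Y}, index in 2..6")
  }
  if ((nrow(fl) == 0L) != (object@kind == "full_metric"))
    msg <- c(msg, "freedLoadings must be empty iff kind = 'full_metric'")
  if (length(msg)) msg else TRUE
})

#' Model-implied moments
#'
#' Per-group model-implied covariance structure with a zero mean vector.
#' Single-level populations yield one 12 x 12 matrix per group; two-level
#' populations yield a within (7 x 7) and a between (7 x 7) matrix per group.
#'
#' @slot matrices named list of symmetric matrices: `sigma` (single level) or
#'   `sigmaW` and `sigmaB` (two level).
#' @slot mean zero mean vector.
#' @slot level `"single"` or `"two"`.
#' @export
setClass("ImpliedMoments",
  representation(matrices = "list", mean = "numeric", level = "character")
)

setValidity("ImpliedMoments", function(object) {
  for (M in object@matrices) {
    if (!isSymmetric(unname(M), tol = 1e-10))
      return("implied covariance matrices must be symmetric")
  }
  ## sigma / sigmaW must be PD; sigmaB is PSD (zero between residuals)
  strict <- object@matrices[names(object@matrices) != "sigmaB"]
  for (M in strict) {
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      return("implied covariance must be positive definite")
  }
  if ("sigmaB" %in% names(object@matrices)) {
    ev <- eigen(object@matrices$sigmaB, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) return("between covariance must be positive semi-definite")
  }
  TRUE
})

## ---- simulation conditions ------------------------------------------------

#' Design-grid conditions
#'
#' A `Study1Condition` holds one cell of the single-level design (number of
#' non-invariant loadings, slope pair, location of non-invariance, per-group
#' sample size); a `Study2Condition` holds one cell of the two-level design
#' (non-invariance, slope pair, intraclass correlation, number of clusters,
#' cluster size).
#'
#' @aliases Study2Condition
#' @seealso [study1Condition()], [study2Condition()], [designGrid()]
#' @export
setClass("Study1Condition",
  representation(pNI = "numeric", gamma = "numeric", location = "character",
                 N = "numeric")
)

setValidity("Study1Condition", function(object) {
  msg <- character(0)
  if (!object@pNI %in% c(0, 2, 4)) msg <- c(msg, "pNI must be 0, 2 or 4")
  ok <- list(c(0.1, 0.1), c(0.5, 0.5), c(0.5, 0.33), c(0.33, 0.5))
  if (!any(vapply(ok, function(g) isTRUE(all.equal(g, object@gamma)), NA)))
    msg <- c(msg, "gamma must be one of {0.1,0.1}, {0.5,0.5}, {0.5,0.33}, {0.33,0.5}")
  if (!object@N %in% c(200, 500)) msg <- c(msg, "N must be 200 or 500")
  if (object@pNI == 0 && object@location != "none")
    msg <- c(msg, "location is undefined (use 'none') when pNI = 0")
  if (object@pNI > 0 && !object@location %in% c("X", "Y"))
    msg <- c(msg, "location must be 'X' or 'Y' when pNI > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname Study1Condition-class
#' @export
setClass("Study2Condition",
  representation(pNI = "numeric", gamma10 = "numeric", icc = "numeric",
                 m = "numeric", clusterSize = "numeric")
)

setValidity("Study2Condition", function(object) {
  msg <- character(0)
  if (!object@pNI %in% c(0, 2)) msg <- c(msg, "pNI must be 0 or 2")
  ok <- list(c(0.3, 0.3), c(0.3, 0.2))
  if (!any(vapply(ok, function(g) isTRUE(all.equal(g, object@gamma10)), NA)))
    msg <- c(msg, "gamma10 must be {0.3,0.3} or {0.3,0.2}")
  if (!object@icc %in% c(0.10, 0.35)) msg <- c(msg, "icc must be 0.10 or 0.35")
  if (!object@m %in% c(30, 100)) msg <- c(msg, "m must be 30 or 100")
  if (!object@clusterSize %in% c(5, 20)) msg <- c(msg, "clusterSize must be 5 or 20")
  if (length(msg)) msg else TRUE
})

## ---- samples --------------------------------------------------------------

#' Generated samples
#'
#' `TwoGroupSample`: one replicate of single-level two-group data (an N x 12
#' indicator matrix per group). `TwoLevelSample`: one replicate of two-group
#' two-level data (an (m*c) x 7 matrix of six indicators plus the outcome per
#' group, with a balanced cluster-id vector).
#'
#' @aliases TwoLevelSample
#' @seealso [generateSingle()], [generateTwoLevel()]
#' @export
setClass("TwoGroupSample",
  representation(data = "list", condition = "Study1Condition", seed = "numeric")
)

setValidity("TwoGroupSample", function(object) {
  if (length(object@data) != 2L) return("data must hold one matrix per group")
  for (d in object@data) {
    if (ncol(d) != 12L) return("each group matrix must have 12 columns")
    if (nrow(d) != object@condition@N) return("row count must equal the condition's N")
    if (!all(is.finite(d))) return("sample values must be finite")
  }
  TRUE
})

#' @rdname TwoGroupSample-class
#' @export
setClass("TwoLevelSample",
  representation(data = "list", cluster = "list", condition = "Study2Condition",
                 seed = "numeric")
)

setValidity("TwoLevelSample", function(object) {
  if (length(object@data) != 2L || length(object@cluster) != 2L)
    return("data and cluster must hold one element per group")
  m <- object@condition@m; cs <- object@condition@clusterSize
  for (g in 1:2) {
    d <- object@data[[g]]; cl <- object@cluster[[g]]
    if (ncol(d) != 7L) return("each group matrix must have 7 columns")
    if (nrow(d) != m * cs) return("row count must equal m * clusterSize")
    tab <- table(cl)
    if (length(tab) != m || !all(tab == cs)) return("clusters must be balanced")
    if (!identical(sort(unique(cl)), seq_len(m))) return("cluster ids must be contiguous 1..m")
  }
  TRUE
})

## ---- sample moments -------------------------------------------------------

#' Sufficient statistics for fitting
#'
#' `TwoGroupMoments` holds per-group ML sample covariance matrices (divisor n)
#' and group sizes. `TwoLevelMoments` holds, per group, the pooled
#' within-cluster covariance S_PW (divisor n - m), the scaled between-cluster
#' covariance S_B (c times the covariance of cluster means, divisor m - 1),
#' the design sizes, and optionally the per-cluster pieces (within SSCP
#' matrices and centered cluster means) needed for cluster-robust standard
#' errors. Fits to population-implied moments carry empty per-cluster pieces
#' and support expected-information standard errors only.
#'
#' @aliases TwoLevelMoments
#' @seealso [momentsOf()], [pooledMomentsTwoLevel()], [populationMoments()]
#' @export
setClass("TwoGroupMoments",
  representation(S = "list", n = "numeric", centered = "list")
)

#' @rdname TwoGroupMoments-class
#' @export
setClass("TwoLevelMoments",
  representation(SPW = "list", SB = "list", m = "numeric", clusterSize = "numeric",
                 n = "numeric", W = "list", ybar = "list")
)

## ---- fit results ----------------------------------------------------------

#' Result of a constrained maximum-likelihood fit
#'
#' @slot estimates named vector of parameter estimates (natural scale).
#' @slot vcov estimate covariance matrix (same order as `estimates`).
#' @slot vcovType `"robust"` (sandwich) or `"expected"` (inverse expected
#'   information).
#' @slot logLik maximized log-likelihood.
#' @slot discrepancy minimized ML discrepancy value.
#' @slot converged logical convergence flag.
#' @slot iterations optimizer iteration count.
#' @slot gradNorm max-norm of the gradient at the solution (transformed scale).
#' @slot heywood TRUE if any variance was floored at the lower bound.
#' @slot contrast named vector: the moderation contrast `delta` (difference of
#'   the two group slopes), its `se`, Wald statistic `W`, `df` and `p`; NA for
#'   equal-slopes fits.
#' @slot scheme the [ConstraintScheme-class] that was fitted.
#' @slot level `"single"` or `"two"`.
#' @slot equalSlopes TRUE if the group slopes were constrained equal.
#' @slot nobs per-group sample sizes.
#' @export
setClass("FitResult",
  representation(
    estimates = "numeric", vcov = "matrix", vcovType = "character",
    logLik = "numeric", discrepancy = "numeric",
    converged = "logical", iterations = "numeric", gradNorm = "numeric",
    heywood = "logical", contrast = "numeric",
    scheme = "ConstraintScheme", level = "character", equalSlopes = "logical",
    nobs = "numeric"
  )
)

setValidity("FitResult", function(object) {
  k <- length(object@estimates)
  if (!all(dim(object@vcov) == c(k, k)))
    return("vcov dimension must match the estimate vector")
  TRUE
})

#' Simulation configuration
#'
#' Bundles the arguments of [runStudy()]: which study, which cells, how many
#' replications, the base seed, the test level, whether to also run the
#' likelihood-ratio test, and an optional output directory for per-cell raw
#' estimates.
#'
#' @seealso [simulationConfig()], [runStudy()]
#' @export
setClass("SimulationConfig",
  representation(study = "numeric", cells = "numeric", reps = "numeric",
                 seed = "numeric", alpha = "numeric", lrt = "logical",
                 outDir = "character")
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (!object@study %in% c(1, 2)) msg <- c(msg, "study must be 1 or 2")
  if (object@reps < 1) msg <- c(msg, "reps must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
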