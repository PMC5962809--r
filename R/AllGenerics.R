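#' Map a design condition to its generating population
#'
#' @param condition a [Study1Condition-class] or [Study2Condition-class].
#' @return a [SingleLevelPopulation-class] or [TwoLevelPopulation-class].
#' @export
setGeneric("populationFor", function(condition) standardGeneric("populationFor"))

#' Model-implied covariance structure
#'
#' Assembles the model-implied covariance matrix (single level: 12 x 12;
#' two level: within and between 7 x 7) for one group of a population, with a
#' zero mean vector.
#'
#' @param population a population object.
#' @param group group index, 1 or 2.
#' @return an [ImpliedMoments-class] object.
#' @export
setGeneric("impliedCov", function(population, group = 1L) standardGeneric("impliedCov"))

#' Sufficient statistics of a generated sample
#'
#' For a [TwoGroupSample-class]: per-group ML covariance matrices (divisor n).
#' For a [TwoLevelSample-class]: the balanced-design pooled-within and scaled
#' between covariance matrices together with the per-cluster pieces used for
#' cluster-robust standard errors.
#'
#' @param x a sample object.
#' @return a [TwoGroupMoments-class] or [TwoLevelMoments-class] object.
#' @export
setGeneric("momentsOf", function(x) standardGeneric("momentsOf"))

#' Fit a constrained two-group structural equation model
#'
#' Minimizes the normal-theory maximum-likelihood discrepancy over the free
#' parameters implied by the constraint scheme. Samples are reduced to their
#' sufficient statistics first; moments objects are fitted directly.
#'
#' @param x a sample or moments object.
#' @param scheme a [ConstraintScheme-class].
#' @param equalSlopes constrain the structural slope equal across groups
#'   (used as the null model of the likelihood-ratio test).
#' @param se `"expected"` for inverse-expected-information standard errors
#'   (the default) or `"robust"` for sandwich standard errors built from
#'   per-observation (or per-cluster) scores. Moments without
#'   per-observation detail fall back to `"expected"`.
#' @param weighting `"ml"` for the exact likelihood; `"moment"` replaces the
#'   two-level between-part log-determinant weight m by m - 1 so that fits to
#'   population-implied moments have their optimum exactly at the supplied
#'   matrices (no effect for single-level fits).
#' @param ... passed to methods.
#' @return a [FitResult-class].
#' @export
setGeneric("fitSEM", function(x, scheme, ...) standardGeneric("fitSEM"))

#' Wald test of the moderation contrast
#'
#' The squared contrast estimate over its estimated variance, referred to the
#' chi-square distribution with one degree of freedom. With a fit object the
#' contrast is the difference of the two group slopes and its variance comes
#' from the estimate covariance via the linear (delta-method) contrast; a
#' contrast estimate and standard error can also be supplied directly.
#'
#' @param fit a converged [FitResult-class], or a numeric contrast estimate.
#' @param ... method arguments; for the numeric method, `se`.
#' @return named vector with `delta`, `se`, `W`, `df`, `p`.
#' @export
setGeneric("waldContrast", function(fit, ...) standardGeneric("waldContrast"))
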