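#' Construct a constraint scheme
#'
#' @param kind `"full_metric"` (all loadings cross-group equal) or
#'   `"partial_metric"` (the listed loadings free per group).
#' @param freedLoadings data.frame with columns `factor` ("X"/"Y") and `index`
#'   (2..6); must be empty iff `kind = "full_metric"`. For two-level models
#'   use factor "X" (the single latent predictor).
#' @return a validated [ConstraintScheme-class].
#' @seealso [fullMetricScheme()], [partialMetricScheme()]
#' @export
constraintScheme <- function(kind = c("full_metric", "partial_metric"),
                             freedLoadings = data.frame(factor = character(0),
                                                        index = integer(0))) {
  kind <- match.arg(kind)
  new("ConstraintScheme", kind = kind,
      freedLoadings = freedLoadings, marker = 0.7)
}

#' The full-metric-invariance ("MI") analysis scheme
#' @export
fullMetricScheme <- function() constraintScheme("full_metric")

#' The partial-metric-invariance ("pMI") scheme matched to a population
#'
#' Frees exactly the loadings that are truly non-invariant in the population
#' (the correctly specified model of the study design).
#'
#' @param population a population (or a design condition, which is resolved
#'   through [populationFor()]) with `pNI > 0`.
#' @export
partialMetricScheme <- function(population) {
  if (is(population, "Study1Condition") || is(population, "Study2Condition"))
    population <- populationFor(population)
  if (population@pNI == 0)
    stop("partial metric invariance is undefined for a fully invariant population")
  idx <- .nonInvariantIdx(population@pNI)
  fac <- if (is(population, "SingleLevelPopulation") && population@location == "Y")
    "Y" else "X"
  constraintScheme("partial_metric",
                   data.frame(factor = fac, index = idx))
}

setMethod("show", "ConstraintScheme", function(object) {
  lab <- if (object@kind == "full_metric") "full metric invariance (MI)"
         else "partial metric invariance (pMI)"
  cat("Constraint scheme:", lab, "\n")
  if (nrow(object@freedLoadings)) {
    cat("  freed loadings:",
        paste(object@freedLoadings$factor, object@freedLoadings$index,
              sep = "", collapse = ", "), "\n")
  }
  cat("  marker loading fixed at", object@marker, "in both groups\n")
})
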