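#' @describeIn waldContrast extract the moderation contrast test from a fit.
#' @export
setMethod("waldContrast", "FitResult", function(fit, ...) {
  if (fit@equalSlopes)
    stop("the moderation contrast is undefined for an equal-slopes fit")
  if (!fit@converged)
    stop("Wald contrast requested from a non-converged fit")
  if (any(is.na(fit@vcov)))
    stop("estimate covariance is unavailable (non-positive-definite information)")
  fit@contrast
})

#' @describeIn waldContrast compute the test from a contrast estimate and its
#'   standard error.
#' @param se standard error of the contrast estimate.
#' @export
setMethod("waldContrast", "numeric", function(fit, se, ...) {
  delta <- fit
  W <- if (se > 0) (delta / se)^2 else if (delta == 0) 0 else Inf
  c(delta = delta, se = se, W = W, df = 1,
    p = pchisq(W, 1, lower.tail = FALSE))
})

#' Likelihood-ratio test of equal slopes
#'
#' `G^2 = 2 (logLik_free - logLik_equal)` for two fits of the same data under
#' the same loading scheme, differing only in whether the structural slope is
#' constrained equal across groups; referred to chi-square with 1 df.
#'
#' The two fits must be nested (same data, same loading scheme); this is the
#' caller's responsibility.
#'
#' @param fitFree fit with group-specific slopes.
#' @param fitEqual fit with the slope constrained equal (`equalSlopes = TRUE`).
#' @param tol small negative `G^2` values within `tol` are clamped to zero
#'   (the models are nested, so the population value is nonnegative).
#' @return named vector with `G2`, `df`, `p`.
#' @export
lrtContrast <- function(fitFree, fitEqual, tol = 1e-6) {
  if (fitFree@level != fitEqual@level)
    stop("fits are not of the same model topology")
  G2 <- 2 * (fitFree@logLik - fitEqual@logLik)
  if (G2 < 0) {
    if (G2 < -tol)
      warning("negative likelihood-ratio statistic (", signif(G2, 4),
              "); check convergence of the nested fits")
    G2 <- 0
  }
  c(G2 = G2, df = 1, p = pchisq(G2, 1, lower.tail = FALSE))
}

## ---- FitResult accessors --------------------------------------------------

#' @describeIn FitResult-class parameter estimates (natural scale).
#' @param object a `FitResult`.
#' @export
setMethod("coef", "FitResult", function(object) object@estimates)

#' @describeIn FitResult-class estimate covariance matrix.
#' @export
setMethod("vcov", "FitResult", function(object) object@vcov)

#' @describeIn FitResult-class maximized log-likelihood.
#' @export
setMethod("logLik", "FitResult", function(object) object@logLik)

#' Did the optimizer converge?
#' @param fit a [FitResult-class].
#' @export
isConverged <- function(fit) fit@converged

#' Flat parameter table of a fit
#'
#' One row per free parameter with its label, estimate and standard error;
#' suitable for writing to comma-separated text.
#'
#' @param fit a [FitResult-class].
#' @export
parameterTable <- function(fit) {
  se <- sqrt(pmax(diag(fit@vcov), 0))
  data.frame(label = names(fit@estimates),
             estimate = unname(fit@estimates),
             se = unname(se))
}

setMethod("show", "FitResult", function(object) {
  cat("Constrained ML fit (", object@level, " level, ",
      object@scheme@kind, if (object@equalSlopes) ", equal slopes" else "",
      ")\n", sep = "")
  cat("  converged:", object@converged,
      " iterations:", object@iterations,
      " logLik:", format(object@logLik, digits = 8), "\n")
  if (object@heywood)
    cat("  note: at least one variance was floored at the lower bound\n")
  if (!object@equalSlopes && object@converged) {
    ct <- object@contrast
    cat(sprintf("  moderation contrast: %.4f (se %.4f), Wald = %.3f, p = %.4f\n",
                ct["delta"], ct["se"], ct["W"], ct["p"]))
  }
})
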